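# Shared fixtures, memoized so expensive objects are built once per run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

# A tiny hand-written three-table cohort (3 patients, 5 visits).
toy_cohort <- function() {
  patients <- tibble::tibble(
    patient_id = c("a", "b", "c"),
    gender = c("F", "M", "F"),
    age = c(50, 70, 30))
  visits <- tibble::tibble(
    patient_id = c("a", "a", "b", "b", "c"),
    visit_id = c("v1", "v2", "v1", "v2", "v1"),
    start_time = as.POSIXct(c("2019-02-04 08:00:00", "2019-02-18 09:00:00",
                              "2019-03-04 10:00:00", "2019-03-11 11:00:00",
                              "2019-04-01 12:00:00"), tz = "UTC"),
    end_time = as.POSIXct(c("2019-02-04 14:00:00", "2019-02-19 09:00:00",
                            "2019-03-05 10:00:00", "2019-03-12 11:00:00",
                            "2019-04-01 18:00:00"), tz = "UTC"),
    event_type = c("ED", "inpatient", "inpatient", "inpatient", "ED"),
    los_total = c(6, 24, 24, 24, 6),
    los_treatment = c(NA, 12, 10, 14, NA))
  diagnoses <- tibble::tibble(
    patient_id = c("a", "a", "a", "b", "b", "c"),
    visit_id = c("v1", "v1", "v2", "v1", "v2", "v1"),
    code = c("J45.0", "Z00.0", "E11.1", "E11.9", "H36.0", "Z00.0"))
  ehr_cohort(patients, visits, diagnoses, toy_schema())
}

toy_schema <- function() {
  cohort_schema(
    static_fields = c(gender = "categorical", age = "continuous",
                      diabetes = "label"),
    visit_fields = c(event_type = "categorical", los_total = "continuous",
                     los_treatment = "continuous"),
    levels = list(gender = c("F", "M"), event_type = c("ED", "inpatient")),
    bands = list(age = c(0, 40, 60, 100), los_total = c(0, 12, 48),
                 los_treatment = c(0, 12, 48)),
    code_systems = list(diagnosis = c("J45.0", "Z00.0", "E11.1", "E11.9",
                                      "H36.0")),
    max_visits = 10,
    study_start = as.Date("2019-01-07"),
    study_end = as.Date("2019-12-31"))
}

# Small simulated cohort shared by several structural tests.
small_sim <- function() memo("small_sim", function() {
  simulate_cohort(sim_config(n_patients = 400, seed = 21))
})

# Prepared (aggregated, split, tokenized) small cohort.
small_prepared <- function() memo("small_prepared", function() {
  sim <- small_sim()
  agg <- aggregate_codes(sim$cohort, min_count = 30)
  parts <- split_cohort(agg$cohort, seed = 3)
  schema <- fit_bands(agg$cohort$schema, parts$train, n_bands = 8)
  for (nm in names(parts)) parts[[nm]]$schema <- schema
  toks <- suppressWarnings(lapply(parts, discretize, schema = schema))
  list(sim = sim, agg = agg, parts = parts, schema = schema, toks = toks)
})

# A deliberately learnable toy pattern: token B always follows token A.
# 200 patients, two visits each; half have A in visit 1 and B in visit 2,
# half have neither.
ab_tokenized <- function() {
  schema <- cohort_schema(
    static_fields = c(gender = "categorical"),
    visit_fields = c(event_type = "categorical"),
    levels = list(gender = c("F", "M"), event_type = c("clinic")),
    code_systems = list(diagnosis = c("AAA", "BBB", "CCC")),
    gap_mode = "start", timestamp_mode = "weekly", max_visits = 4,
    study_start = as.Date("2019-01-07"), study_end = as.Date("2019-12-30"))
  n <- 200
  start <- rep(as.POSIXct("2019-02-04 08:00:00", tz = "UTC"), 2)
  mk <- function(i) {
    with_a <- i %% 2 == 0
    pid <- sprintf("p%03d", i)
    list(
      patients = tibble::tibble(patient_id = pid,
                                gender = c("F", "M")[i %% 2 + 1]),
      visits = tibble::tibble(patient_id = pid, visit_id = c("v1", "v2"),
                              start_time = start + c(0, 14 * 86400),
                              event_type = "clinic"),
      diagnoses = if (with_a) tibble::tibble(
        patient_id = pid, visit_id = c("v1", "v1", "v2"),
        code = c("AAA", "CCC", "BBB")) else tibble::tibble(
          patient_id = pid, visit_id = "v1", code = "CCC"))
  }
  all <- lapply(seq_len(n), mk)
  cohort <- ehr_cohort(dplyr::bind_rows(lapply(all, `[[`, "patients")),
                       dplyr::bind_rows(lapply(all, `[[`, "visits")),
                       dplyr::bind_rows(lapply(all, `[[`, "diagnoses")),
                       schema)
  discretize(cohort, schema)
}

# Small trained engine on the A->B pattern (few seconds).
ab_model <- function() memo("ab_model", function() {
  tok <- ab_tokenized()
  ids <- names(tok$records)
  tr <- tok; tr$records <- tok$records[1:160]
  va <- tok; va$records <- tok$records[161:200]
  train_engine(tr, va, engine_config(n_layers = 2, embedding_dim = 32,
                                     n_heads = 4, epochs = 30,
                                     batch_size = 32, learning_rate = 5e-3,
                                     seed = 11))
})

# TSTR fixture shared between the utility tests and the identity suite.
tstr_fixture <- function() memo("tstr", function() {
  sim <- memo("sim5000", function()
    simulate_cohort(sim_config(n_patients = 5000, seed = 77)))
  parts <- split_cohort(sim$cohort, c(train = 0.6, validation = 0.2,
                                      test = 0.2), seed = 9)
  task <- task_condition_label("diabetes")
  res <- tstr_evaluate(parts$train, parts$validation, parts$test, task,
                       seed = 3)
  list(parts = parts, task = task, res = res)
})

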