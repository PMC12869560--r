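test_that("every comparison metric returns its identity value on self-comparison", {
  sim <- small_sim()
  co <- sim$cohort
  st <- summary_compare(co, co)
  expect_equal(st$real, st$synth)
  cf <- correlation_fidelity(co, co)
  expect_equal(cf$max_abs_diff, 0)
  expect_true(all(cf$corr_diff == 0 | is.na(cf$corr_diff)))
  fq <- code_frequency_r2(co, co)
  expect_equal(fq$r2, 1)
  expect_equal(fq$retained_fraction, 1)
  expect_equal(bigram_r2(co, co, "within_visit"), 1)
  expect_equal(bigram_r2(co, co, "sequential_visits"), 1)
  tf <- temporal_fidelity(co, co, max_lag = 14)
  expect_equal(tf$lag7_contrast, 0)
  rep <- comparison_report(co, co, max_lag = 14)
  td <- tidy(rep)
  expect_equal(td$value[td$metric == "freq_r2"], 1)
  expect_equal(td$value[td$metric == "lag7_contrast"], 0)
})

test_that("summary statistics match hand-computed values on a toy cohort", {
  co <- toy_cohort()
  st <- summary_compare(co, co)
  pick <- function(v, s) st$real[st$variable == v & st$statistic == s]
  expect_equal(pick("age", "mean"), mean(c(50, 70, 30)))
  expect_equal(pick("age", "sd"), stats::sd(c(50, 70, 30)))
  expect_equal(pick("gender", "pct_female"), 100 * 2 / 3)
  expect_equal(pick("visits_per_patient", "median"), 2)
  expect_equal(pick("diagnosis_codes", "n_unique"), 5)
  one <- ehr_cohort(co$patients[1, ], co$visits[1, ], co$diagnoses[1, ],
                    co$schema)
  st1 <- summary_compare(one, one)
  expect_equal(st1$real[st1$variable == "age" & st1$statistic == "mean"], 50)
  expect_equal(st1$real[st1$variable == "age" & st1$statistic == "sd"],
               NA_real_)
})

test_that("correlation fidelity flags independence and perfect dependence", {
  set.seed(8)
  n <- 10000
  mk <- function(y_from_x = FALSE) {
    pat <- tibble::tibble(patient_id = sprintf("p%05d", 1:n),
                          gender = "F", age = stats::rnorm(n, 50, 10))
    x <- stats::rnorm(n)
    vis <- tibble::tibble(
      patient_id = pat$patient_id, visit_id = "v1",
      start_time = as.POSIXct("2019-01-07", tz = "UTC"),
      event_type = "ED", u = x,
      w = if (y_from_x) 2 * x + 1 else stats::rnorm(n))
    ehr_cohort(pat, vis, tibble::tibble(patient_id = character(0),
                                        visit_id = character(0),
                                        code = character(0)))
  }
  ind <- mk(FALSE)
  cf <- correlation_fidelity(ind, ind, variables = c("u", "w"))
  expect_lt(abs(cf$corr_real["u", "w"]), 0.05)
  dep <- mk(TRUE)
  cf2 <- correlation_fidelity(dep, dep, variables = c("u", "w"))
  expect_equal(unname(cf2$corr_real["u", "w"]), 1)
})

test_that("code frequency R2 matches a least-squares oracle on a toy table", {
  mkc <- function(counts) {
    n <- sum(counts)
    ehr_cohort(
      tibble::tibble(patient_id = "p1", gender = "F", age = 1),
      tibble::tibble(patient_id = "p1", visit_id = "v1",
                     start_time = as.POSIXct("2019-01-07", tz = "UTC"),
                     event_type = "ED"),
      tibble::tibble(patient_id = "p1",
                     visit_id = "v1",
                     code = rep(names(counts), counts)))
  }
  real <- mkc(c(A = 50, B = 25, C = 12, D = 8, E = 5))
  synth <- mkc(c(A = 40, B = 30, C = 15, D = 10, E = 5))
  got <- code_frequency_r2(real, synth, log_scale = FALSE)
  fr <- c(50, 25, 12, 8, 5) / 100
  fs <- c(40, 30, 15, 10, 5) / 100
  expect_equal(got$r2, summary(stats::lm(fs ~ fr))$r.squared)
  expect_equal(got$retained_fraction, 1)
  half <- mkc(c(A = 40, B = 30))
  expect_equal(code_frequency_r2(real, half)$retained_fraction, 0.4)
})

test_that("bigram probabilities match exhaustive enumeration on small cohorts", {
  brute <- function(cohort, mode) {
    sets <- visit_code_sets(cohort)
    vis <- dplyr::arrange(cohort$visits, .data$patient_id, .data$start_time)
    out <- list()
    if (mode == "within_visit") {
      codes <- sort(unique(cohort$diagnoses$code))
      for (a in codes) for (b in codes) {
        if (a >= b) next
        cnt <- sum(vapply(sets, function(s) a %in% s && b %in% s,
                          logical(1)))
        if (cnt > 0) out[[paste(a, b, sep = "\r")]] <- cnt / length(sets)
      }
    } else {
      codes <- sort(unique(cohort$diagnoses$code))
      npairs <- 0
      cnt <- list()
      for (pid in unique(vis$patient_id)) {
        rows <- which(vis$patient_id == pid)
        if (length(rows) < 2) next
        npairs <- npairs + length(rows) - 1
        for (t in seq_len(length(rows) - 1)) {
          for (a in sets[[rows[t]]]) for (b in sets[[rows[t + 1]]]) {
            key <- paste(a, b, sep = "\r")
            cnt[[key]] <- (cnt[[key]] %||% 0) + 1
          }
        }
      }
      for (key in names(cnt)) out[[key]] <- cnt[[key]] / npairs
    }
    unlist(out)
  }
  set.seed(9)
  for (i in 1:3) {
    cfg <- sim_config(n_patients = 6, seed = 30 + i)
    co <- simulate_cohort(cfg)$cohort
    for (mode in c("within_visit", "sequential_visits")) {
      got <- bigram_probs(co, mode)
      want <- brute(co, mode)
      expect_equal(got[sort(names(got))], want[sort(names(want))],
                   tolerance = 1e-12)
    }
  }
  # disjoint vocabularies score zero
  mk1 <- function(code) ehr_cohort(
    tibble::tibble(patient_id = c("p1", "p2"), gender = "F", age = 1),
    tibble::tibble(patient_id = c("p1", "p1", "p2"),
                   visit_id = c("v1", "v2", "v1"),
                   start_time = as.POSIXct("2019-01-07", tz = "UTC") +
                     c(0, 86400, 0),
                   event_type = "ED"),
    tibble::tibble(patient_id = c("p1", "p1", "p1", "p2"),
                   visit_id = c("v1", "v1", "v2", "v1"),
                   code = paste0(code, 1:4)))
  expect_equal(bigram_r2(mk1("X"), mk1("Y"), "within_visit"), 0)
})

test_that("conditional occurrence follows the strictly-later-visit rule", {
  mk <- function(dx) ehr_cohort(
    tibble::tibble(patient_id = c("A", "B"), gender = "F", age = 1),
    tibble::tibble(patient_id = rep(c("A", "B"), each = 3),
                   visit_id = rep(c("v1", "v2", "v3"), 2),
                   start_time = rep(as.POSIXct("2019-01-07", tz = "UTC") +
                                      (0:2) * 86400, 2),
                   event_type = "ED"),
    dx)
  # A: index visit 1, outcome visit 3; B: neither
  co <- mk(tibble::tibble(patient_id = c("A", "A"),
                          visit_id = c("v1", "v3"),
                          code = c("IDX", "OUT")))
  got <- conditional_occurrence(co, "IDX", "OUT")
  expect_equal(got$p_with, 1)
  expect_equal(got$p_without, 0)
  # outcome only in the same visit as index never counts
  co2 <- mk(tibble::tibble(patient_id = c("A", "A"),
                           visit_id = c("v2", "v2"),
                           code = c("IDX", "OUT")))
  expect_equal(conditional_occurrence(co2, "IDX", "OUT")$p_with, 0)
})

test_that("simulated progression probability is recovered at scale", {
  sim <- memo("sim5000", function()
    simulate_cohort(sim_config(n_patients = 5000, seed = 77)))
  co <- conditional_occurrence(sim$cohort, "E11.1", "H36.0")
  expect_lt(abs(co$p_with - 0.6),
            3 * sqrt(0.6 * 0.4 / attr(co, "n_with_index")))
  expect_equal(co$p_without, 0)
})

test_that("conditional cohort checks report prevalences and demographics", {
  sim <- small_sim()
  co <- sim$cohort
  carriers <- unique(co$diagnoses$patient_id[startsWith(co$diagnoses$code,
                                                        "E11")])
  cond <- subset_patients(co, carriers)
  got <- conditional_cohort_check(cond, co, co, c("E11.1", "E11.2", "E11.9"))
  expect_equal(unname(got$prevalence["conditioned"]), 1)
  expect_equal(unname(got$prevalence["unconditioned"]),
               unname(got$prevalence["real"]))
  expect_equal(got$demographics$n[1], length(carriers))
  expect_error(conditional_cohort_check(
    subset_patients(co, character(0)), co, co, "E11.1"), "empty")
})

test_that("coefficient comparison recovers generative truth and identity", {
  set.seed(10)
  n <- 5000
  mkreg <- function() {
    x <- stats::runif(n, 0, 10)
    grp <- sample(c("A", "B", "C"), n, replace = TRUE)
    eff <- c(A = 0, B = 1, C = 2.5)
    y <- 2 * x + eff[grp] + stats::rnorm(n, 0, 1)
    pat <- tibble::tibble(patient_id = sprintf("p%05d", 1:n), gender = "F",
                          age = 1)
    vis <- tibble::tibble(patient_id = pat$patient_id, visit_id = "v1",
                          start_time = as.POSIXct("2019-01-07", tz = "UTC"),
                          event_type = "ED", x = x, grp = grp, y = y)
    ehr_cohort(pat, vis, tibble::tibble(patient_id = character(0),
                                        visit_id = character(0),
                                        code = character(0)))
  }
  r1 <- mkreg(); r2 <- mkreg()
  spec <- list(formula = y ~ x + grp, family = "gaussian")
  tab <- coefficient_comparison(r1, r1, spec)
  expect_equal(tab$est_real, tab$est_synth)
  tab2 <- coefficient_comparison(r1, r2, spec)
  expect_lt(abs(tab2$est_real[tab2$term == "x"] - 2), 0.1)
  expect_true(all(tab2$sign_agree[tab2$term != "(Intercept)"]))
  expect_true(attr(tab2, "ordering_preserved")$grp)
})

test_that("prevalence curves recover monotone age trends", {
  sim <- memo("sim5000", function()
    simulate_cohort(sim_config(n_patients = 5000, seed = 77)))
  co <- sim$cohort
  pc <- prevalence_curves(co, co,
                          list(dementia = "F03.9",
                               heart = c("I21.0", "I21.9")))
  expect_true(all(pc$max_gap == 0))
  dem <- pc$curves[pc$curves$condition == "dementia", ]
  rho <- stats::cor(dem$age_mid, dem$prev_real, method = "spearman")
  expect_gt(rho, 0.9)
  # a condition absent from synth gaps by the real curve maximum
  empty <- co
  empty$diagnoses <- co$diagnoses[!startsWith(co$diagnoses$code, "F03"), ]
  pc2 <- prevalence_curves(co, empty, list(dementia = "F03.9"))
  expect_equal(unname(pc2$max_gap["dementia"]),
               max(pc2$curves$prev_real))
})

test_that("temporal fidelity detects weekly structure and its absence", {
  set.seed(11)
  mkdaily <- function(pattern) {
    days <- seq(as.Date("2019-01-07"), by = "day", length.out = 364)
    lam <- if (pattern) ifelse(lubridate::wday(days, week_start = 1) <= 5,
                               15, 3) else rep(8, length(days))
    cnt <- stats::rpois(length(days), lam)
    pid <- sprintf("p%06d", seq_len(sum(cnt)))
    vis <- tibble::tibble(
      patient_id = pid, visit_id = "v1",
      start_time = as.POSIXct(rep(days, cnt), tz = "UTC"),
      event_type = "ED")
    ehr_cohort(tibble::tibble(patient_id = pid, gender = "F", age = 1),
               vis,
               tibble::tibble(patient_id = character(0),
                              visit_id = character(0), code = character(0)))
  }
  weekly <- mkdaily(TRUE); flat <- mkdaily(FALSE)
  tf <- temporal_fidelity(weekly, flat, max_lag = 30)
  expect_gt(tf$acf_real[7], 0.5)
  # white noise stays inside the Bartlett band at most lags
  bart <- 2 / sqrt(364)
  expect_gt(mean(abs(tf$acf_synth) < bart), 0.85)
  expect_gt(tf$lag7_contrast, 0.4)
  expect_error(temporal_fidelity(weekly, flat, max_lag = 400), "span")
})
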