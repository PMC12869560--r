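# Ground-truth cohort simulator: a generator with known statistical
# structure standing in for restricted clinical datasets, so that every
# pipeline stage and evaluation metric has a recoverable truth.

#' Configuration of the ground-truth cohort simulator
#'
#' Defaults emulate a Queensland-style emergency/inpatient administrative
#' extract at desk scale: irregular visit timing with weekday/weekend and
#' seasonal intensity structure, heterogeneous visit counts, ICD-shaped
#' diagnosis codes with demographic-dependent condition families,
#' within-visit code co-occurrence lifts, a later-visit progression rule,
#' a correlated length-of-stay pair with log-normal marginals and a known
#' Pearson correlation, occasional overlapping episodes (small negative
#' discharge-to-admission gaps), and informative missingness (treatment
#' length of stay exists only for inpatient visits, plus a small
#' missing-at-random rate).
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed (byte-identical cohorts per seed).
#' @param study_start Monday anchoring week 0.
#' @param n_weeks Study window length in weeks.
#' @param age_mean,age_sd,age_range Truncated-normal age distribution.
#' @param p_female Probability of female gender.
#' @param event_probs Named probabilities over event types.
#' @param weekly_weights Seven nonnegative day-of-week intensity weights
#'   (Monday first).
#' @param seasonal_amplitude Relative amplitude of the sinusoidal yearly
#'   intensity component.
#' @param visit_lambda Visits per patient are `1 + Poisson(visit_lambda)`,
#'   capped at `max_visits`.
#' @param max_visits Visit cap.
#' @param overlap_prob Probability that a later admission starts before
#'   the previous discharge (negative gap mixture component).
#' @param overlap_max_hours Maximal overlap depth in hours.
#' @param conditions Data frame of condition families (name, prefix,
#'   codes, family code weights, baseline patient prevalence, age and
#'   gender log-odds coefficients, per-visit expression probability).
#' @param filler_codes Named per-visit prevalences of unconditional codes.
#' @param cooccurrence List of `list(a =, b =, lift =)` within-visit lifts.
#' @param progression `list(index =, outcome =, prob =)`: the outcome code
#'   is planted in one uniformly chosen later visit with probability
#'   `prob` for patients whose index code occurs in a non-final visit (the
#'   outcome code has no other source).
#' @param los_meanlog,los_sdlog Log-normal parameters of total and
#'   treatment length of stay (hours) on inpatient visits.
#' @param los_target_r Target Pearson correlation of the pair (the
#'   Gaussian-copula correlation is derived in closed form).
#' @param ed_meanlog,ed_sdlog Log-normal ED duration (hours).
#' @param missing_rate_treatment Extra missing-at-random rate for
#'   treatment length of stay on inpatient visits.
#' @param start_hour_weights 24 nonnegative admission-hour weights.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 2000L, seed = 1L,
                       study_start = as.Date("2019-01-07"),
                       n_weeks = 104L,
                       age_mean = 50, age_sd = 20, age_range = c(0, 95),
                       p_female = 0.5,
                       event_probs = c(ED = 0.6, inpatient = 0.4),
                       weekly_weights = c(2, 2, 2, 2, 2, 1, 1),
                       seasonal_amplitude = 0.3,
                       visit_lambda = 2,
                       max_visits = 10L,
                       overlap_prob = 0.02,
                       overlap_max_hours = 48,
                       conditions = default_sim_conditions(),
                       filler_codes = default_sim_fillers(),
                       cooccurrence = default_sim_cooccurrence(),
                       progression = list(index = "E11.1", outcome = "H36.0",
                                          prob = 0.6),
                       los_meanlog = c(3.5, 3.0), los_sdlog = c(1.0, 0.8),
                       los_target_r = 0.7,
                       ed_meanlog = 1.2, ed_sdlog = 0.5,
                       missing_rate_treatment = 0.05,
                       start_hour_weights = stats::dnorm(0:23, 12, 4) + 0.02) {
  stopifnot(all(weekly_weights >= 0), any(weekly_weights > 0),
            abs(sum(event_probs) - 1) < 1e-8,
            los_target_r > -1, los_target_r < 1,
            progression$prob >= 0, progression$prob <= 1)
  rho <- lognormal_copula_rho(los_target_r, los_sdlog[1], los_sdlog[2])
  for (cc in cooccurrence) {
    pb <- filler_codes[[cc$b]]
    if (!is.null(pb) && cc$lift * pb > 1)
      stop("infeasible co-occurrence lift for ", cc$b,
           ": lifted probability exceeds 1")
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 study_start = study_start, n_weeks = as.integer(n_weeks),
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 p_female = p_female, event_probs = event_probs,
                 weekly_weights = weekly_weights,
                 seasonal_amplitude = seasonal_amplitude,
                 visit_lambda = visit_lambda,
                 max_visits = as.integer(max_visits),
                 overlap_prob = overlap_prob,
                 overlap_max_hours = overlap_max_hours,
                 conditions = conditions, filler_codes = filler_codes,
                 cooccurrence = cooccurrence, progression = progression,
                 los_meanlog = los_meanlog, los_sdlog = los_sdlog,
                 los_target_r = los_target_r, los_copula_rho = rho,
                 ed_meanlog = ed_meanlog, ed_sdlog = ed_sdlog,
                 missing_rate_treatment = missing_rate_treatment,
                 start_hour_weights = start_hour_weights),
            class = "sim_config")
}

prog_index_code <- function(config) config$progression$index

# Gaussian-copula correlation giving a target Pearson r for a bivariate
# log-normal pair: r = (exp(rho*s1*s2) - 1) / sqrt((e^{s1^2}-1)(e^{s2^2}-1)).
lognormal_copula_rho <- function(target_r, s1, s2) {
  v <- target_r * sqrt(expm1(s1^2) * expm1(s2^2))
  rho <- log1p(v) / (s1 * s2)
  if (abs(rho) >= 1) stop("target correlation infeasible for these sdlogs")
  rho
}

#' @rdname sim_config
#' @export
default_sim_conditions <- function() {
  tibble::tribble(
    ~name,          ~prefix, ~codes,                        ~weights,        ~base_p, ~age_coef, ~female_coef, ~expr_p,
    "asthma",        "J45",  list(c("J45.0", "J45.9")),     list(c(.6, .4)), 0.10,    -0.4,      0.0,          0.45,
    "diabetes",      "E11",  list(c("E11.1", "E11.2", "E11.9")), list(c(.4, .3, .3)), 0.15, 0.5, 0.0,         0.45,
    "heart_disease", "I21",  list(c("I21.0", "I21.9")),     list(c(.5, .5)), 0.08,    0.7,       -0.2,         0.40,
    "dementia",      "F03",  list(c("F03.9")),              list(1),         0.04,    1.0,       0.0,          0.40,
    "stroke",        "I63",  list(c("I63.9")),              list(1),         0.05,    0.6,       0.0,          0.35,
    "cancer",        "C50",  list(c("C50.9")),              list(1),         0.06,    0.3,       0.5,          0.40
  )
}

#' @rdname sim_config
#' @export
default_sim_fillers <- function() {
  c(Z00.0 = 0.30, R07.4 = 0.20, M54.5 = 0.15, R10.4 = 0.12, K35.8 = 0.10,
    N39.0 = 0.09, A09.9 = 0.08, G43.9 = 0.07, S72.0 = 0.06, L03.9 = 0.05,
    B34.9 = 0.04, T14.8 = 0.03)
}

#' @rdname sim_config
#' @export
default_sim_cooccurrence <- function() {
  list(list(a = "Z00.0", b = "R07.4", lift = 2),
       list(a = "M54.5", b = "R10.4", lift = 2),
       list(a = "K35.8", b = "A09.9", lift = 2.5))
}

sim_code_vocabulary <- function(config) {
  sort(unique(c(unlist(config$conditions$codes),
                names(config$filler_codes),
                config$progression$outcome)))
}

#' Cohort schema matching the simulator's output
#' @param config A [sim_config()].
#' @return A [cohort_schema()] (continuous bands unset; fit with
#'   [fit_bands()] on a training split).
#' @export
sim_schema <- function(config) {
  labels <- stats::setNames(rep("label", nrow(config$conditions)),
                            config$conditions$name)
  cohort_schema(
    static_fields = c(c(gender = "categorical", age = "continuous"), labels),
    visit_fields = c(event_type = "categorical", los_total = "continuous",
                     los_treatment = "continuous"),
    levels = list(gender = c("F", "M"),
                  event_type = names(config$event_probs)),
    code_systems = list(diagnosis = sim_code_vocabulary(config)),
    gap_mode = "discharge",
    timestamp_mode = "admission",
    max_visits = config$max_visits,
    study_start = config$study_start,
    study_end = config$study_start + config$n_weeks * 7L - 1L
  )
}

#' Simulate a ground-truth cohort with known structure
#'
#' Draws patients per the configuration: visit dates from a day-of-week
#' and seasonally weighted point process over the study window, diagnosis
#' codes from demographic-dependent condition families, filler
#' prevalences and co-occurrence lifts, the progression rule applied to a
#' later visit, the correlated log-normal length-of-stay pair, informative
#' and random missingness, and static condition labels derived from the
#' code families actually present. Reproducible for a given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (an [ehr_cohort()]), `schema`
#'   ([sim_schema()]) and `truth` (the configured parameters plus derived
#'   closed-form expectations used by [truth_check()]).
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_patients
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  oob <- age < config$age_range[1] | age > config$age_range[2]
  while (any(oob)) {
    age[oob] <- stats::rnorm(sum(oob), config$age_mean, config$age_sd)
    oob <- age < config$age_range[1] | age > config$age_range[2]
  }
  female <- stats::runif(n) < config$p_female
  gender <- ifelse(female, "F", "M")
  k <- pmin(1L + stats::rpois(n, config$visit_lambda), config$max_visits)

  # patient-level condition assignment (logistic in age and gender)
  cond <- config$conditions
  cell <- function(x) if (is.list(x) && length(x) == 1) x[[1]] else x
  has_cond <- matrix(FALSE, n, nrow(cond))
  colnames(has_cond) <- cond$name
  for (j in seq_len(nrow(cond))) {
    eta <- stats::qlogis(cond$base_p[j]) +
      cond$age_coef[j] * (age - 50) / 10 +
      cond$female_coef[j] * female
    has_cond[, j] <- stats::runif(n) < stats::plogis(eta)
  }

  # visit dates: weighted (week, day) cells
  ww <- 1 + config$seasonal_amplitude *
    sin(2 * pi * (seq_len(config$n_weeks) - 1) / 52)
  dw <- config$weekly_weights / sum(config$weekly_weights)
  cellw <- as.vector(outer(ww, dw))     # week-major: cell = (week, dow)
  total_visits <- sum(k)
  cells <- sample.int(length(cellw), total_visits, replace = TRUE,
                      prob = cellw)
  week <- (cells - 1) %% config$n_weeks
  dow <- (cells - 1) %/% config$n_weeks + 1
  hour <- sample.int(24, total_visits, replace = TRUE,
                     prob = config$start_hour_weights) - 1L
  minute <- sample.int(60, total_visits, replace = TRUE) - 1L
  start <- as.POSIXct(config$study_start, tz = "UTC") +
    ((week * 7 + (dow - 1)) * 24 + hour) * 3600 + minute * 60
  pid_of_visit <- rep(seq_len(n), k)
  ord <- order(pid_of_visit, start)
  start <- start[ord]

  etype <- sample(names(config$event_probs), total_visits, replace = TRUE,
                  prob = config$event_probs)
  inp <- etype == "inpatient"
  # correlated log-normal LOS pair on inpatient visits
  z1 <- stats::rnorm(total_visits)
  z2 <- config$los_copula_rho * z1 +
    sqrt(1 - config$los_copula_rho^2) * stats::rnorm(total_visits)
  los_total <- ifelse(inp,
                      exp(config$los_meanlog[1] + config$los_sdlog[1] * z1),
                      exp(config$ed_meanlog + config$ed_sdlog *
                            stats::rnorm(total_visits)))
  los_treatment <- ifelse(inp,
                          exp(config$los_meanlog[2] +
                                config$los_sdlog[2] * z2), NA_real_)
  los_treatment[inp & stats::runif(total_visits) <
                  config$missing_rate_treatment] <- NA_real_
  end <- start + los_total * 3600

  # overlapping episodes: pull some admissions before the previous discharge
  visit_seq <- stats::ave(seq_along(start), pid_of_visit[ord],
                          FUN = seq_along)
  cand <- which(visit_seq > 1 & stats::runif(total_visits) <
                  config$overlap_prob)
  for (i in cand) {
    newstart <- end[i - 1] - stats::runif(1, 0, config$overlap_max_hours) * 3600
    if (newstart > start[i - 1]) {
      delta <- as.numeric(newstart) - as.numeric(start[i])
      start[i] <- newstart
      end[i] <- end[i] + delta
    }
  }

  # diagnosis codes
  pid_sorted <- pid_of_visit[ord]
  dx_pid <- integer(0); dx_vseq <- integer(0); dx_code <- character(0)
  add_dx <- function(vidx, codes) {
    dx_pid <<- c(dx_pid, pid_sorted[vidx])
    dx_vseq <<- c(dx_vseq, visit_seq[vidx])
    dx_code <<- c(dx_code, codes)
  }
  # filler codes with co-occurrence lifts
  lift_b <- vapply(config$cooccurrence, function(x) x$b, character(1))
  lift_a <- vapply(config$cooccurrence, function(x) x$a, character(1))
  lifts <- vapply(config$cooccurrence, function(x) x$lift, numeric(1))
  present_a <- list()
  for (code in names(config$filler_codes)) {
    p <- config$filler_codes[[code]]
    if (code %in% lift_b) next
    on <- stats::runif(total_visits) < p
    present_a[[code]] <- on
    if (any(on)) add_dx(which(on), rep(code, sum(on)))
  }
  for (j in seq_along(lift_b)) {
    pb <- config$filler_codes[[lift_b[j]]]
    a_on <- present_a[[lift_a[j]]]
    pr <- ifelse(a_on, pmin(1, lifts[j] * pb), pb)
    on <- stats::runif(total_visits) < pr
    if (any(on)) add_dx(which(on), rep(lift_b[j], sum(on)))
  }
  # condition family codes
  for (j in seq_len(nrow(cond))) {
    carriers <- has_cond[pid_sorted, j]
    on <- carriers & stats::runif(total_visits) < cond$expr_p[j]
    if (any(on)) {
      codes <- sample(cell(cond$codes[[j]]), sum(on), replace = TRUE,
                      prob = cell(cond$weights[[j]]))
      # the progression index code never occurs in a patient's final
      # visit, so "index ever present" implies a later visit exists and
      # the progression probability is recoverable as stated
      is_final <- visit_seq[which(on)] == k[pid_sorted[which(on)]]
      swap <- codes == prog_index_code(config) & is_final
      if (any(swap)) {
        alt <- setdiff(cell(cond$codes[[j]]), prog_index_code(config))
        if (length(alt) > 0) codes[swap] <- alt[1]
      }
      add_dx(which(on), codes)
    }
  }
  # progression rule: outcome planted in one uniformly chosen later visit
  prog <- config$progression
  idx_rows <- dx_code == prog$index
  idx_pat <- unique(dx_pid[idx_rows])
  planted <- 0L
  plant_vidx <- integer(0)
  for (p in idx_pat) {
    first_idx_visit <- min(dx_vseq[idx_rows & dx_pid == p])
    kp <- k[p]
    if (first_idx_visit >= kp) next   # index only allowed a later visit
    if (stats::runif(1) < prog$prob) {
      target <- if (kp - first_idx_visit == 1) kp else
        sample((first_idx_visit + 1):kp, 1)
      plant_vidx <- c(plant_vidx,
                      which(pid_sorted == p & visit_seq == target))
      planted <- planted + 1L
    }
  }
  if (planted > 0) add_dx(plant_vidx, rep(prog$outcome, planted))

  # static labels derive from the code families actually present
  patients <- tibble::tibble(patient_id = sprintf("p%05d", seq_len(n)),
                             gender = gender, age = age)
  fam_present <- matrix(FALSE, n, nrow(cond))
  for (j in seq_len(nrow(cond))) {
    fam <- startsWith(dx_code, cond$prefix[j])
    fam_present[unique(dx_pid[fam]), j] <- TRUE
  }
  for (j in seq_len(nrow(cond)))
    patients[[cond$name[j]]] <- as.integer(fam_present[, j])

  visits <- tibble::tibble(
    patient_id = sprintf("p%05d", pid_sorted),
    visit_id = sprintf("v%02d", visit_seq),
    start_time = start, end_time = end,
    event_type = etype, los_total = los_total,
    los_treatment = los_treatment)
  diagnoses <- tibble::tibble(patient_id = sprintf("p%05d", dx_pid),
                              visit_id = sprintf("v%02d", dx_vseq),
                              code = dx_code)
  diagnoses <- dplyr::distinct(diagnoses)

  schema <- sim_schema(config)
  cohort <- ehr_cohort(patients, visits, diagnoses, schema)
  fillers_marginal <- config$filler_codes
  for (j in seq_along(lift_b)) {
    pa <- config$filler_codes[[lift_a[j]]]
    pb <- config$filler_codes[[lift_b[j]]]
    fillers_marginal[[lift_b[j]]] <- pb + pa * pb * (lifts[j] - 1)
  }
  truth <- list(config = config,
                weekday_weekend_ratio = config$weekly_weights[1] /
                  config$weekly_weights[7],
                los_pearson_r = config$los_target_r,
                progression_prob = config$progression$prob,
                filler_marginals = fillers_marginal,
                p_female = config$p_female,
                n_outcome_planted = planted)
  list(cohort = cohort, schema = schema, truth = truth)
}

#' Re-estimate configured simulator parameters from a cohort
#'
#' The simulator module's own acceptance gate: each configured parameter
#' is recovered from the simulated cohort and compared with its truth at
#' a Monte-Carlo tolerance (3 binomial/Fisher-z standard errors, floored
#' for very small counts).
#'
#' @param cohort Cohort from [simulate_cohort()].
#' @param truth Matching truth record.
#' @return Tibble with columns `parameter`, `truth`, `estimate`,
#'   `tolerance`, `ok`.
#' @export
truth_check <- function(cohort, truth) {
  config <- truth$config
  rows <- list()
  addrow <- function(parameter, tr, est, tol) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      parameter = parameter, truth = tr, estimate = est, tolerance = tol,
      ok = abs(est - tr) <= tol)
  }
  n <- nrow(cohort$patients)
  pf <- mean(cohort$patients$gender == "F")
  addrow("p_female", config$p_female, pf,
         3 * sqrt(config$p_female * (1 - config$p_female) / n))
  # weekday:weekend intensity ratio of daily counts
  dow <- lubridate::wday(cohort$visits$start_time, week_start = 1)
  wkday <- mean(tabulate(dow, 7)[1:5])
  wkend <- mean(tabulate(dow, 7)[6:7])
  ratio <- wkday / wkend
  addrow("weekday_weekend_ratio", truth$weekday_weekend_ratio, ratio,
         max(0.15, 6 * ratio / sqrt(length(dow))))
  # Pearson correlation of the inpatient LOS pair (Fisher-z tolerance)
  pair <- cohort$visits[cohort$visits$event_type == "inpatient", ]
  cc <- stats::complete.cases(pair$los_total, pair$los_treatment)
  if (sum(cc) > 10) {
    r <- stats::cor(pair$los_total[cc], pair$los_treatment[cc])
    # log-normal Pearson r has heavier sampling error than Fisher z on
    # bivariate normal data; use z-tolerance with an inflation factor
    ztol <- 3 * 2.5 / sqrt(sum(cc) - 3)
    addrow("los_pearson_r", truth$los_pearson_r, r, max(0.05, ztol))
  }
  # progression probability via conditional occurrence
  co <- conditional_occurrence(cohort, config$progression$index,
                               config$progression$outcome)
  n_idx <- attr(co, "n_with_index")
  if (n_idx > 0) {
    addrow("progression_prob", truth$progression_prob, co$p_with,
           max(0.03, 3 * sqrt(truth$progression_prob *
                                (1 - truth$progression_prob) / n_idx)))
  }
  # filler marginal per-visit prevalences (first three)
  nv <- nrow(cohort$visits)
  vkey <- paste(cohort$visits$patient_id, cohort$visits$visit_id)
  for (code in names(truth$filler_marginals)[1:3]) {
    p <- truth$filler_marginals[[code]]
    hits <- length(unique(paste(cohort$diagnoses$patient_id,
                                cohort$diagnoses$visit_id)[
                                  cohort$diagnoses$code == code]))
    addrow(paste0("prevalence_", code), p, hits / nv,
           max(0.007, 3 * sqrt(p * (1 - p) / nv)))
  }
  addrow("age_mean", config$age_mean, mean(cohort$patients$age),
         3 * config$age_sd / sqrt(n) + 0.3)
  dplyr::bind_rows(rows)
}
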