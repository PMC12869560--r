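# Realism metrics comparing a synthetic cohort with a real one.

cohort_analysis_rows <- function(cohort, variables = NULL) {
  vis <- dplyr::arrange(cohort$visits, .data$patient_id, .data$start_time)
  gap_mode <- if (!is.null(cohort$schema)) cohort$schema$gap_mode else "start"
  vis$gap_days <- compute_gaps(vis, gap_mode)
  rows <- dplyr::left_join(vis, cohort$patients, by = "patient_id")
  if (!is.null(variables)) {
    keep <- intersect(c("patient_id", variables), names(rows))
    rows <- rows[, keep, drop = FALSE]
  }
  rows
}

#' Side-by-side summary statistics for two cohorts
#'
#' Per-variable mean/sd and median/IQR/range for age, the continuous visit
#' variables and days between visits, plus percent female, visits per
#' patient and unique diagnosis code counts — the standard shape of a
#' synthetic-data summary table.
#'
#' @param real,synth [ehr_cohort()] objects sharing a schema.
#' @param variables Optional restriction of the continuous variables.
#' @return Tibble with columns `variable`, `statistic`, `real`, `synth`.
#' @export
summary_compare <- function(real, synth, variables = NULL) {
  one <- function(cohort) {
    rows <- list()
    put <- function(variable, statistic, value)
      rows[[length(rows) + 1]] <<- tibble::tibble(
        variable = variable, statistic = statistic, value = value)
    num_stats <- function(v, x) {
      x <- x[is.finite(x)]
      if (length(x) == 0) return()
      put(v, "mean", mean(x)); put(v, "sd", stats::sd(x))
      put(v, "median", stats::median(x))
      put(v, "q25", unname(stats::quantile(x, .25)))
      put(v, "q75", unname(stats::quantile(x, .75)))
      put(v, "min", min(x)); put(v, "max", max(x))
    }
    pat <- cohort$patients
    if ("age" %in% names(pat)) num_stats("age", pat$age)
    if ("gender" %in% names(pat))
      put("gender", "pct_female", 100 * mean(pat$gender == "F"))
    vpp <- table(factor(cohort$visits$patient_id,
                        levels = pat$patient_id))
    num_stats("visits_per_patient", as.numeric(vpp))
    rows_v <- cohort_analysis_rows(cohort)
    num_stats("days_between_visits", rows_v$gap_days)
    cont <- variables %||% setdiff(
      names(cohort$visits),
      c("patient_id", "visit_id", "start_time", "end_time", "event_type",
        "visit_seq"))
    for (v in cont) {
      if (v %in% names(cohort$visits) && is.numeric(cohort$visits[[v]]))
        num_stats(v, cohort$visits[[v]])
    }
    put("diagnosis_codes", "n_unique",
        length(unique(cohort$diagnoses$code)))
    dplyr::bind_rows(rows)
  }
  a <- dplyr::rename(one(real), real = "value")
  b <- dplyr::rename(one(synth), synth = "value")
  dplyr::full_join(a, b, by = c("variable", "statistic"))
}

#' Pairwise correlation fidelity between two cohorts
#'
#' Pearson correlations over patient-visit rows (each visit joined with
#' its patient's statics, plus the inter-visit gap), the synthetic minus
#' real difference matrix and its largest absolute entry. Constant
#' variables yield missing cells.
#'
#' @param real,synth [ehr_cohort()] objects.
#' @param variables Numeric variables to correlate; defaults to every
#'   shared numeric column.
#' @return List `corr_real`, `corr_synth`, `corr_diff`, `max_abs_diff`.
#' @export
correlation_fidelity <- function(real, synth, variables = NULL) {
  mat <- function(cohort) {
    rows <- cohort_analysis_rows(cohort)
    num <- vapply(rows, is.numeric, logical(1))
    v <- variables %||% setdiff(names(rows)[num], "visit_seq")
    as.matrix(rows[, intersect(v, names(rows)[num]), drop = FALSE])
  }
  mr <- mat(real); ms <- mat(synth)
  shared <- intersect(colnames(mr), colnames(ms))
  if (length(shared) < 2) stop("need at least two shared numeric variables")
  suppressWarnings({
    cr <- stats::cor(mr[, shared], use = "pairwise.complete.obs")
    cs <- stats::cor(ms[, shared], use = "pairwise.complete.obs")
  })
  cd <- cs - cr
  off <- abs(cd[upper.tri(cd)])
  list(corr_real = cr, corr_synth = cs, corr_diff = cd,
       max_abs_diff = if (all(is.na(off))) NA_real_ else max(off, na.rm = TRUE))
}

#' Diagnosis-code frequency agreement
#'
#' Relative per-code occurrence frequencies over the codes present in the
#' real cohort (codes absent from the synthetic cohort enter at frequency
#' zero, floored on the log scale at half the smallest nonzero synthetic
#' frequency), compared as the least-squares R-squared (squared Pearson
#' correlation), by default on log10 frequencies. Also reports the
#' fraction of real codes retained in the synthetic cohort.
#'
#' @param real,synth [ehr_cohort()] objects.
#' @param log_scale Compare log10 frequencies (default) or raw ones.
#' @return List `r2`, `retained_fraction`.
#' @export
code_frequency_r2 <- function(real, synth, log_scale = TRUE) {
  fr_tab <- table(real$diagnoses$code)
  if (length(fr_tab) == 0) stop("real cohort has no diagnosis codes")
  fs_tab <- table(synth$diagnoses$code)
  codes <- names(fr_tab)
  fr <- as.numeric(fr_tab) / sum(fr_tab)
  fs <- as.numeric(fs_tab[codes])
  fs[is.na(fs)] <- 0
  fs <- fs / max(sum(fs_tab), 1)
  retained <- mean(codes %in% names(fs_tab))
  if (log_scale) {
    eps <- if (any(fs > 0)) min(fs[fs > 0]) / 2 else 1e-6
    x <- log10(fr); y <- log10(pmax(fs, eps))
  } else {
    x <- fr; y <- fs
  }
  r2 <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    if (isTRUE(all.equal(x, y))) 1 else 0
  } else stats::cor(x, y)^2
  list(r2 = r2, retained_fraction = retained)
}

visit_code_sets <- function(cohort) {
  vis <- dplyr::arrange(cohort$visits, .data$patient_id, .data$start_time)
  key <- paste(vis$patient_id, vis$visit_id)
  dkey <- paste(cohort$diagnoses$patient_id, cohort$diagnoses$visit_id)
  sets <- split(cohort$diagnoses$code, factor(dkey, levels = key))
  lapply(sets, unique)
}

bigram_probs <- function(cohort, mode) {
  sets <- visit_code_sets(cohort)
  pid <- dplyr::arrange(cohort$visits, .data$patient_id,
                        .data$start_time)$patient_id
  if (mode == "within_visit") {
    n_visits <- length(sets)
    pairs <- character(0)
    for (s in sets) {
      s <- sort(s)
      if (length(s) >= 2) {
        cmb <- utils::combn(s, 2)
        pairs <- c(pairs, paste(cmb[1, ], cmb[2, ], sep = "\r"))
      }
    }
    tab <- table(pairs)
    stats::setNames(as.numeric(tab) / n_visits, names(tab))
  } else {
    n_pairs <- 0L
    pairs <- character(0)
    idx_by_pat <- split(seq_along(sets), pid)
    for (vv in idx_by_pat) {
      if (length(vv) < 2) next
      n_pairs <- n_pairs + length(vv) - 1L
      for (t in seq_len(length(vv) - 1)) {
        a <- sets[[vv[t]]]; b <- sets[[vv[t + 1]]]
        if (length(a) > 0 && length(b) > 0)
          pairs <- c(pairs, paste(rep(a, each = length(b)), b, sep = "\r"))
      }
    }
    if (n_pairs == 0)
      stop("no multi-visit patients: sequential bigram undefined")
    tab <- table(pairs)
    stats::setNames(as.numeric(tab) / n_pairs, names(tab))
  }
}

#' Diagnosis-code bigram agreement between cohorts
#'
#' Within-visit mode: for each unordered code pair, the fraction of visits
#' containing both. Sequential mode: for each ordered pair `(a, b)`, the
#' fraction of consecutive visit pairs with `a` in the earlier and `b` in
#' the later visit. Probabilities are compared over the union support as
#' the squared Pearson correlation of the two probability vectors, with
#' anti-correlated vectors scored 0 (`max(0, cor)^2`), so that
#' self-comparison gives exactly 1 and disjoint vocabularies give 0.
#'
#' @param real,synth [ehr_cohort()] objects.
#' @param mode `"within_visit"` or `"sequential_visits"`.
#' @return R-squared in `[0, 1]`.
#' @export
bigram_r2 <- function(real, synth, mode = c("within_visit",
                                            "sequential_visits")) {
  mode <- match.arg(mode)
  pr <- bigram_probs(real, mode)
  ps <- bigram_probs(synth, mode)
  support <- union(names(pr), names(ps))
  if (length(support) == 0) return(1)
  r <- ifelse(support %in% names(pr), pr[support], 0)
  s <- ifelse(support %in% names(ps), ps[support], 0)
  if (stats::sd(r) == 0 || stats::sd(s) == 0)
    return(if (isTRUE(all.equal(r, s))) 1 else 0)
  max(0, stats::cor(r, s))^2
}

#' Conditional occurrence of an outcome diagnosis after an index diagnosis
#'
#' `p_with` is the fraction of patients with any index code whose any
#' strictly later visit contains an outcome code; `p_without` the fraction
#' of patients never carrying an index code who ever have an outcome code.
#'
#' @param cohort An [ehr_cohort()].
#' @param index_dx_set,outcome_dx_set Nonempty character code sets.
#' @return List `p_with`, `p_without` (patient counts attached as
#'   attributes `n_with_index` / `n_without_index`).
#' @export
conditional_occurrence <- function(cohort, index_dx_set, outcome_dx_set) {
  stopifnot(length(index_dx_set) > 0, length(outcome_dx_set) > 0)
  vis <- dplyr::arrange(cohort$visits, .data$patient_id, .data$start_time)
  vis$.seq <- stats::ave(seq_len(nrow(vis)), vis$patient_id, FUN = seq_along)
  dx <- cohort$diagnoses
  dx$.seq <- vis$.seq[match(paste(dx$patient_id, dx$visit_id),
                            paste(vis$patient_id, vis$visit_id))]
  dx <- dx[!is.na(dx$.seq), ]
  per <- dplyr::summarise(
    dplyr::group_by(dx, .data$patient_id),
    first_index = suppressWarnings(min(.data$.seq[.data$code %in%
                                                    index_dx_set])),
    any_outcome = any(.data$code %in% outcome_dx_set),
    outcome_after = any(.data$code %in% outcome_dx_set &
                          .data$.seq > .data$first_index[1]),
    .groups = "drop")
  all_ids <- unique(cohort$patients$patient_id)
  with_idx <- per$patient_id[is.finite(per$first_index)]
  without_idx <- setdiff(all_ids, with_idx)
  p_with <- if (length(with_idx) == 0) NA_real_ else
    mean(per$outcome_after[is.finite(per$first_index)])
  out_ids <- per$patient_id[per$any_outcome]
  p_without <- if (length(without_idx) == 0) NA_real_ else
    mean(without_idx %in% out_ids)
  structure(list(p_with = p_with, p_without = p_without),
            n_with_index = length(with_idx),
            n_without_index = length(without_idx))
}

#' Prevalence and demographic checks for conditionally generated cohorts
#'
#' Reports the prevalence of a condition code set in the conditioned
#' synthetic cohort, the unconditioned synthetic cohort and the real
#' cohort, together with mean age, percent female and median visit count
#' of the conditioned cohort versus real patients having the condition.
#'
#' @param synth_conditioned,synth_unconditioned,real [ehr_cohort()]
#'   objects sharing a schema.
#' @param condition_code_set Character codes defining the condition.
#' @return List with `prevalence` (named triple) and `demographics`
#'   (tibble comparing the conditioned cohort with real condition
#'   carriers).
#' @export
conditional_cohort_check <- function(synth_conditioned, synth_unconditioned,
                                     real, condition_code_set) {
  if (nrow(synth_conditioned$patients) == 0)
    stop("empty conditioned cohort")
  prev <- function(cohort) {
    carriers <- unique(cohort$diagnoses$patient_id[
      cohort$diagnoses$code %in% condition_code_set])
    length(carriers) / nrow(cohort$patients)
  }
  demo <- function(cohort, only_carriers = FALSE) {
    pat <- cohort$patients
    if (only_carriers) {
      carriers <- unique(cohort$diagnoses$patient_id[
        cohort$diagnoses$code %in% condition_code_set])
      pat <- pat[pat$patient_id %in% carriers, ]
    }
    vpp <- table(factor(cohort$visits$patient_id, levels = pat$patient_id))
    tibble::tibble(mean_age = mean(pat$age, na.rm = TRUE),
                   pct_female = 100 * mean(pat$gender == "F", na.rm = TRUE),
                   median_visits = stats::median(as.numeric(vpp)),
                   n = nrow(pat))
  }
  list(prevalence = c(conditioned = prev(synth_conditioned),
                      unconditioned = prev(synth_unconditioned),
                      real = prev(real)),
       demographics = dplyr::bind_rows(
         conditioned = demo(synth_conditioned),
         real_with_condition = demo(real, TRUE), .id = "cohort"))
}

#' Compare regression coefficients fitted on real and synthetic data
#'
#' Fits the same specification (linear or binomial, optionally with a
#' random intercept via lme4) to both cohorts and pairs the fixed-effect
#' estimates with 95% Wald intervals, flagging sign agreement per term and
#' whether the ordering of each factor's level estimates is preserved.
#'
#' @param real,synth [ehr_cohort()] objects.
#' @param model_spec List with `formula`, `family` (`"gaussian"` or
#'   `"binomial"`), and optionally `data_fn(cohort)` returning the
#'   analysis table (default: visits joined with patient statics plus
#'   `gap_days`).
#' @return Tibble of paired estimates; per-factor ordering flags attached
#'   as attribute `"ordering_preserved"`, convergence notes as
#'   `"convergence"`.
#' @export
coefficient_comparison <- function(real, synth, model_spec) {
  data_fn <- model_spec$data_fn %||% cohort_analysis_rows
  family <- model_spec$family %||% "gaussian"
  fit_one <- function(cohort) {
    df <- data_fn(cohort)
    has_bars <- length(lme4::findbars(model_spec$formula)) > 0
    fit <- tryCatch({
      if (has_bars) {
        if (family == "gaussian")
          lme4::lmer(model_spec$formula, data = df, REML = FALSE)
        else
          lme4::glmer(model_spec$formula, data = df, family = stats::binomial())
      } else {
        if (family == "gaussian") stats::lm(model_spec$formula, data = df)
        else stats::glm(model_spec$formula, data = df,
                        family = stats::binomial())
      }
    }, error = function(e) e)
    if (inherits(fit, "error"))
      return(list(ok = FALSE, msg = conditionMessage(fit)))
    sm <- if (inherits(fit, "merMod")) {
      cf <- lme4::fixef(fit)
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))
      tibble::tibble(term = names(cf), estimate = unname(cf), se = se)
    } else {
      cf <- summary(fit)$coefficients
      tibble::tibble(term = rownames(cf), estimate = cf[, 1], se = cf[, 2])
    }
    list(ok = TRUE, coefs = sm)
  }
  fr <- fit_one(real)
  fs <- fit_one(synth)
  conv <- c(real = if (fr$ok) "ok" else fr$msg,
            synth = if (fs$ok) "ok" else fs$msg)
  if (!fr$ok || !fs$ok) {
    out <- tibble::tibble(term = character(0))
    attr(out, "convergence") <- conv
    return(out)
  }
  tab <- dplyr::full_join(
    dplyr::rename(fr$coefs, est_real = "estimate", se_real = "se"),
    dplyr::rename(fs$coefs, est_synth = "estimate", se_synth = "se"),
    by = "term")
  tab <- dplyr::mutate(tab,
    lo_real = .data$est_real - 1.96 * .data$se_real,
    hi_real = .data$est_real + 1.96 * .data$se_real,
    lo_synth = .data$est_synth - 1.96 * .data$se_synth,
    hi_synth = .data$est_synth + 1.96 * .data$se_synth,
    sign_agree = sign(.data$est_real) == sign(.data$est_synth))
  # ordering of factor-level estimates
  facs <- all.vars(model_spec$formula)[-1]
  ordering <- list()
  for (v in facs) {
    lv_terms <- tab$term[startsWith(tab$term, v) & tab$term != v]
    if (length(lv_terms) >= 2) {
      o_r <- order(tab$est_real[match(lv_terms, tab$term)])
      o_s <- order(tab$est_synth[match(lv_terms, tab$term)])
      ordering[[v]] <- identical(o_r, o_s)
    }
  }
  attr(tab, "ordering_preserved") <- ordering
  attr(tab, "convergence") <- conv
  tab
}

#' Condition prevalence by gender and age in both cohorts
#'
#' Patient-level condition flags (any code in the set) are modelled per
#' gender with a binned logistic smoother over age (a binomial GLM on age
#' bins); fitted prevalences are compared and the maximum absolute gap
#' per condition reported.
#'
#' @param real,synth [ehr_cohort()] objects with `age` and `gender`.
#' @param condition_code_sets Named list of character code sets.
#' @param age_bins Numeric age bin edges.
#' @return List with `curves` (tibble: condition, gender, age bin,
#'   fitted prevalence per cohort) and `max_gap` (named numeric).
#' @export
prevalence_curves <- function(real, synth, condition_code_sets,
                              age_bins = seq(0, 100, by = 10)) {
  fit_curves <- function(cohort, codes) {
    pat <- cohort$patients
    carriers <- unique(cohort$diagnoses$patient_id[
      cohort$diagnoses$code %in% codes])
    df <- tibble::tibble(
      flag = as.integer(pat$patient_id %in% carriers),
      gender = as.character(pat$gender),
      bin = cut(pat$age, age_bins, right = FALSE, include.lowest = TRUE))
    df <- df[!is.na(df$bin), ]
    out <- list()
    for (g in sort(unique(df$gender))) {
      d <- df[df$gender == g, ]
      d$bin <- droplevels(d$bin)
      if (nrow(d) == 0 || length(unique(d$flag)) == 0) next
      fit <- suppressWarnings(
        stats::glm(flag ~ bin, data = d, family = stats::binomial()))
      nd <- tibble::tibble(bin = factor(levels(d$bin), levels(d$bin)))
      out[[g]] <- tibble::tibble(
        gender = g, age_bin = as.character(nd$bin),
        age_mid = vapply(levels(d$bin), bin_mid, numeric(1)),
        prevalence = as.numeric(suppressWarnings(
          stats::predict(fit, nd, type = "response"))))
    }
    dplyr::bind_rows(out)
  }
  curves <- list()
  max_gap <- numeric(0)
  for (cn in names(condition_code_sets)) {
    cr <- fit_curves(real, condition_code_sets[[cn]])
    cs <- fit_curves(synth, condition_code_sets[[cn]])
    if (nrow(cr) == 0) next
    m <- dplyr::full_join(dplyr::rename(cr, prev_real = "prevalence"),
                          dplyr::rename(cs, prev_synth = "prevalence"),
                          by = c("gender", "age_bin", "age_mid"))
    m$prev_synth[is.na(m$prev_synth)] <- 0
    m$condition <- cn
    curves[[cn]] <- m
    max_gap[cn] <- max(abs(m$prev_synth - m$prev_real), na.rm = TRUE)
  }
  list(curves = dplyr::bind_rows(curves), max_gap = max_gap)
}

bin_mid <- function(lab) {
  nums <- as.numeric(strsplit(gsub("\\[|\\]|\\(|\\)", "", lab), ",")[[1]])
  mean(nums)
}

#' Aggregate temporal fidelity via daily-count autocorrelation
#'
#' Daily event counts per cohort (optionally one event type), their sample
#' ACF and PACF to `max_lag`, and the lag-7 ACF contrast
#' `acf_real[7] - acf_synth[7]` capturing how much of the weekly
#' periodicity survives in the synthetic data.
#'
#' @param real,synth [ehr_cohort()] objects with calendar dates.
#' @param event_type Optional event type filter.
#' @param max_lag Maximum lag in days (at least 7).
#' @return List `acf_real`, `acf_synth`, `pacf_real`, `pacf_synth`
#'   (vectors indexed by lag 1..max_lag), `lag7_contrast`.
#' @export
temporal_fidelity <- function(real, synth, event_type = NULL, max_lag = 30) {
  stopifnot(max_lag >= 7)
  daily <- function(cohort) {
    vis <- cohort$visits
    if (!is.null(event_type)) vis <- vis[vis$event_type %in% event_type, ]
    d <- as.Date(vis$start_time, tz = "UTC")
    span <- seq(min(d), max(d), by = "day")
    if (length(span) < max_lag + 2)
      stop("date span shorter than max_lag + 2 days")
    as.numeric(table(factor(as.character(d), levels = as.character(span))))
  }
  xr <- daily(real); xs <- daily(synth)
  af <- function(x) as.numeric(stats::acf(x, lag.max = max_lag,
                                          plot = FALSE)$acf)[-1]
  pf <- function(x) as.numeric(stats::pacf(x, lag.max = max_lag,
                                           plot = FALSE)$acf)
  ar <- af(xr); as_ <- af(xs)
  list(acf_real = ar, acf_synth = as_, pacf_real = pf(xr),
       pacf_synth = pf(xs), lag7_contrast = ar[7] - as_[7])
}

#' Full realism comparison report
#'
#' Runs the distributional, correlation, code-frequency, bigram,
#' conditional-occurrence and temporal metrics and collects them in one
#' object with [generics::tidy()] and [ggplot2::autoplot()] support.
#'
#' @param real,synth [ehr_cohort()] objects.
#' @param variables Optional numeric variables for the correlation block.
#' @param condition_pairs Optional named list of
#'   `list(index =, outcome =)` code sets for conditional occurrence.
#' @param max_lag Lag bound for the temporal block (`NULL` skips it, e.g.
#'   when either cohort lacks usable dates).
#' @return A `comparison_report`.
#' @export
comparison_report <- function(real, synth, variables = NULL,
                              condition_pairs = NULL, max_lag = 30) {
  cf <- code_frequency_r2(real, synth)
  rep <- list(
    summary_table = summary_compare(real, synth),
    correlation = correlation_fidelity(real, synth, variables),
    freq_r2 = cf$r2,
    retained_fraction = cf$retained_fraction,
    bigram_r2_within = bigram_r2(real, synth, "within_visit"),
    bigram_r2_sequential = tryCatch(
      bigram_r2(real, synth, "sequential_visits"),
      error = function(e) NA_real_),
    conditional_occurrence = NULL,
    temporal = NULL
  )
  if (!is.null(condition_pairs)) {
    rep$conditional_occurrence <- purrr::map_dfr(
      names(condition_pairs), function(nm) {
        pr <- condition_pairs[[nm]]
        a <- conditional_occurrence(real, pr$index, pr$outcome)
        b <- conditional_occurrence(synth, pr$index, pr$outcome)
        tibble::tibble(pair = nm,
                       p_with_real = a$p_with, p_without_real = a$p_without,
                       p_with_synth = b$p_with,
                       p_without_synth = b$p_without)
      })
  }
  if (!is.null(max_lag)) {
    rep$temporal <- tryCatch(temporal_fidelity(real, synth,
                                               max_lag = max_lag),
                             error = function(e) NULL)
  }
  structure(rep, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat("  code frequency R2:", format(x$freq_r2, digits = 3),
      " (retained ", format(100 * x$retained_fraction, digits = 3), "%)\n",
      sep = "")
  cat("  bigram R2 within/sequential: ",
      format(x$bigram_r2_within, digits = 3), " / ",
      format(x$bigram_r2_sequential, digits = 3), "\n", sep = "")
  cat("  max |corr diff|: ",
      format(x$correlation$max_abs_diff, digits = 3), "\n", sep = "")
  if (!is.null(x$temporal))
    cat("  lag-7 ACF contrast: ",
        format(x$temporal$lag7_contrast, digits = 3), "\n", sep = "")
  invisible(x)
}
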