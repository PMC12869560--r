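# Calendar reconstruction: start-week sampling, day-of-week draws, and the
# multi-tier admission/discharge logic.

#' Fit calendar lookup tables from a training cohort
#'
#' Builds (i) the bijective week-index -> calendar-week-start lookup over
#' the schema's study window (weeks indexed from the Monday of the start
#' week), (ii) the empirical day-of-week distribution of visits, (iii)
#' KDE-derived start-week grids stratified by the patient's total visit
#' count, and (iv) empirical start-hour and end-hour/day tables used by the
#' admission/discharge tiers.
#'
#' @param cohort Training [ehr_cohort()].
#' @param schema A [cohort_schema()].
#' @param min_stratum_n Visit-count strata smaller than this fall back to
#'   the pooled start-week grid.
#' @param stratum_cap Visit counts at or above this are pooled into one
#'   stratum.
#' @return A `calendar_maps` object.
#' @export
fit_calendar_maps <- function(cohort, schema, min_stratum_n = 30L,
                              stratum_cap = 6L) {
  monday0 <- lubridate::floor_date(schema$study_start, "week", week_start = 1)
  n_weeks <- as.integer(ceiling(as.numeric(
    schema$study_end - monday0 + 1) / 7))
  vis <- cohort$visits
  wk <- week_index(vis$start_time, monday0)
  dow <- lubridate::wday(vis$start_time, week_start = 1)
  dow_probs <- tabulate(dow, 7) / length(dow)
  first <- dplyr::summarise(
    dplyr::group_by(vis, .data$patient_id),
    start_week = week_index(min(.data$start_time), monday0),
    n_visits = dplyr::n(), .groups = "drop")
  strat <- visit_count_stratum(first$n_visits, stratum_cap)
  start_week_grid <- fit_marginal_kde(first$start_week, strat,
                                      grid_resolution = 1,
                                      min_stratum_n = min_stratum_n,
                                      variable = "start_week")
  start_hour_probs <- hour_table(lubridate::hour(vis$start_time))
  has_end <- !is.na(vis$end_time)
  end_hour_probs <- if (any(has_end))
    hour_table(lubridate::hour(vis$end_time[has_end])) else rep(1 / 24, 24)
  end_dow_probs <- if (any(has_end))
    tabulate(lubridate::wday(vis$end_time[has_end], week_start = 1), 7) /
      sum(has_end) else rep(1 / 7, 7)
  structure(list(monday0 = monday0, n_weeks = n_weeks,
                 dow_probs = dow_probs,
                 start_week_grid = start_week_grid,
                 start_hour_probs = start_hour_probs,
                 end_hour_probs = end_hour_probs,
                 end_dow_probs = end_dow_probs,
                 stratum_cap = stratum_cap),
            class = "calendar_maps")
}

week_index <- function(time, monday0) {
  d <- as.Date(time, tz = "UTC")
  as.integer(floor(as.numeric(d - monday0) / 7))
}

visit_count_stratum <- function(n_visits, cap) {
  ifelse(n_visits >= cap, paste0(cap, "+"), as.character(n_visits))
}

hour_table <- function(hours) tabulate(hours + 1, 24) / length(hours)

week_to_date <- function(cal, week, dow) {
  clamped <- pmin(pmax(week, 0L), cal$n_weeks - 1L)
  n_clamped <- sum(clamped != week, na.rm = TRUE)
  structure(cal$monday0 + clamped * 7L + (dow - 1L), n_clamped = n_clamped)
}

#' Assign calendar start dates to synthetic patients (weekly mode)
#'
#' For each patient a plausible starting week is sampled from the
#' KDE-derived start-week grid of the stratum matching the patient's total
#' visit count; per-visit days of week are drawn from the empirical
#' distribution; visit `i`'s week is the start week plus the cumulative
#' inter-visit gap weeks; `(week, day)` is mapped to a calendar date
#' through the lookup table (clamped to the study window if a cumulative
#' week falls outside, with a flag count).
#'
#' @param visits Tibble with `patient_id`, `visit_seq` and `gap_weeks`
#'   (integer weeks since the previous visit; `NA` for the first visit).
#' @param calendar_maps A [fit_calendar_maps()] result.
#' @return `visits` with added `week`, `dow`, `start_date` and `clamped`
#'   columns (`clamped` marks rows whose cumulative week fell outside the
#'   study window and was pulled to its edge); the clamp count is also
#'   attached as attribute `"n_clamped"`.
#' @export
reconstruct_visit_dates <- function(visits, calendar_maps) {
  cal <- calendar_maps
  visits <- dplyr::arrange(visits, .data$patient_id, .data$visit_seq)
  pat <- dplyr::summarise(dplyr::group_by(visits, .data$patient_id),
                          n_visits = dplyr::n(), .groups = "drop")
  strat <- visit_count_stratum(pat$n_visits, cal$stratum_cap)
  start_week <- integer(nrow(pat))
  for (s in unique(strat)) {
    idx <- which(strat == s)
    # band = full grid range: stage-1/stage-2 draw over the whole support
    g <- cal$start_week_grid$grid
    v <- sample_within_band(c(g[1], g[length(g)]), cal$start_week_grid,
                            stratum = s, n = length(idx))
    start_week[idx] <- as.integer(floor(v))
  }
  gw <- visits$gap_weeks
  gw[is.na(gw)] <- 0L
  cum <- stats::ave(gw, visits$patient_id, FUN = cumsum)
  week <- start_week[match(visits$patient_id, pat$patient_id)] + cum
  dow <- sample.int(7, nrow(visits), replace = TRUE, prob = cal$dow_probs)
  dates <- week_to_date(cal, week, dow)
  visits$week <- pmin(pmax(week, 0L), cal$n_weeks - 1L)
  visits$clamped <- week != visits$week
  visits$dow <- dow
  visits$start_date <- as.Date(dates)
  attr(visits, "n_clamped") <- attr(dates, "n_clamped")
  visits
}

round_half_up <- function(x) floor(x + 0.5)

#' Derive discharge times from admission time and length of stay
#'
#' Three tiers by length of stay: up to 24 hours, discharge is admission
#' plus the stay; between 1 and 7 days, the stay is converted to integer
#' days (round half up) and the time of day set to the synthetic end hour;
#' over 7 days, the stay is converted to weeks and the discharge date read
#' from the week/day lookup, adjusted with the end hour. Discharge is
#' never allowed before admission.
#'
#' @param admission_time POSIXct vector.
#' @param los_hours Nonnegative length of stay in hours.
#' @param end_hour,end_week,end_dow Optional synthetic event-timing values
#'   (vectors, NA elements are sampled from / derived with the calendar
#'   maps: end hour and end day of week from their empirical tables, end
#'   week from the admission week plus the stay in whole weeks).
#' @param calendar_maps A [fit_calendar_maps()] result.
#' @return POSIXct vector of discharge times.
#' @export
derive_discharge <- function(admission_time, los_hours, end_hour = NA,
                             end_week = NA, end_dow = NA, calendar_maps) {
  cal <- calendar_maps
  n <- length(admission_time)
  stopifnot(length(los_hours) == n)
  end_hour <- rep_len(end_hour, n)
  end_week <- rep_len(end_week, n)
  end_dow <- rep_len(end_dow, n)
  need_h <- is.na(end_hour) & !is.na(los_hours) & los_hours > 24
  end_hour[need_h] <- sample.int(24, sum(need_h), replace = TRUE,
                                 prob = cal$end_hour_probs) - 1L
  out <- as.POSIXct(rep(NA_real_, n), origin = "1970-01-01", tz = "UTC")
  t1 <- !is.na(los_hours) & los_hours <= 24
  out[t1] <- admission_time[t1] + los_hours[t1] * 3600
  t2 <- !is.na(los_hours) & los_hours > 24 & los_hours <= 168
  if (any(t2)) {
    d <- as.Date(admission_time[t2], tz = "UTC") +
      round_half_up(los_hours[t2] / 24)
    out[t2] <- as.POSIXct(d, tz = "UTC") + end_hour[t2] * 3600
  }
  t3 <- !is.na(los_hours) & los_hours > 168
  if (any(t3)) {
    wk <- end_week[t3]
    need <- is.na(wk)
    wk[need] <- week_index(admission_time[t3][need], cal$monday0) +
      round_half_up(los_hours[t3][need] / 168)
    dw <- end_dow[t3]
    needd <- is.na(dw)
    dw[needd] <- sample.int(7, sum(needd), replace = TRUE,
                            prob = cal$end_dow_probs)
    d <- week_to_date(cal, wk, dw)
    out[t3] <- as.POSIXct(as.Date(d), tz = "UTC") + end_hour[t3] * 3600
  }
  pmax(out, admission_time)
}

#' Derive a subsequent admission time from the previous discharge
#'
#' Mirrors the three discharge tiers, driven by the inter-visit interval
#' instead of the length of stay: intervals up to 24 hours (including the
#' small negative values of the overlap band) are added directly;
#' intervals of 1 to 7 days set the date by whole days and the time of day
#' to a synthetic start hour; longer intervals go through the week/day
#' lookup. Out-of-order start times produced by overlap intervals are
#' expected to be repaired afterwards by a stable sort on start time.
#'
#' @param prev_discharge POSIXct vector.
#' @param interval_days Inter-visit interval in days (may be slightly
#'   negative for overlapping episodes).
#' @param start_hour,event_week,event_dow Optional synthetic timing values
#'   (NAs sampled from / derived with the calendar maps).
#' @param calendar_maps A [fit_calendar_maps()] result.
#' @return POSIXct vector of admission times.
#' @export
derive_next_admission <- function(prev_discharge, interval_days,
                                  start_hour = NA, event_week = NA,
                                  event_dow = NA, calendar_maps) {
  cal <- calendar_maps
  n <- length(prev_discharge)
  iv_h <- interval_days * 24
  start_hour <- rep_len(start_hour, n)
  event_week <- rep_len(event_week, n)
  event_dow <- rep_len(event_dow, n)
  need_h <- is.na(start_hour) & !is.na(iv_h) & iv_h > 24
  start_hour[need_h] <- sample.int(24, sum(need_h), replace = TRUE,
                                   prob = cal$start_hour_probs) - 1L
  out <- as.POSIXct(rep(NA_real_, n), origin = "1970-01-01", tz = "UTC")
  t1 <- !is.na(iv_h) & iv_h <= 24
  out[t1] <- prev_discharge[t1] + iv_h[t1] * 3600
  t2 <- !is.na(iv_h) & iv_h > 24 & iv_h <= 168
  if (any(t2)) {
    d <- as.Date(prev_discharge[t2], tz = "UTC") +
      round_half_up(iv_h[t2] / 24)
    out[t2] <- as.POSIXct(d, tz = "UTC") + start_hour[t2] * 3600
  }
  t3 <- !is.na(iv_h) & iv_h > 168
  if (any(t3)) {
    wk <- event_week[t3]
    need <- is.na(wk)
    wk[need] <- week_index(prev_discharge[t3][need], cal$monday0) +
      round_half_up(iv_h[t3][need] / 168)
    dw <- event_dow[t3]
    needd <- is.na(dw)
    dw[needd] <- sample.int(7, sum(needd), replace = TRUE,
                            prob = cal$dow_probs)
    d <- week_to_date(cal, wk, dw)
    out[t3] <- as.POSIXct(as.Date(d), tz = "UTC") + start_hour[t3] * 3600
  }
  out
}
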