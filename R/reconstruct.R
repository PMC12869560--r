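# Fitting and applying the post-processing state that turns tokenized
# synthetic output back into dated, full-resolution three-table cohorts.

#' Fit the reconstruction state from a training cohort
#'
#' Builds everything the post-processing step needs: stratified marginal
#' KDE grids for each continuous variable (statics stratified by
#' `static_strata`, visit variables by `visit_strata`), an optional joint
#' KDE grid for a correlated pair, a KDE grid for the inter-visit gap
#' variable, the calendar lookup maps, and the code aggregation map for
#' re-expansion.
#'
#' @param cohort Training [ehr_cohort()].
#' @param schema A [cohort_schema()] with fitted bands.
#' @param aggregation_map Optional `code_aggregation_map` from
#'   [aggregate_codes()].
#' @param joint_pair Character pair of visit variables to reconstruct
#'   jointly (`NULL` disables; the default picks
#'   `c("los_total", "los_treatment")` when both exist).
#' @param static_strata,visit_strata Stratifying columns (e.g. gender and
#'   event type); `NULL` disables stratification.
#' @param los_field Visit variable holding length of stay in hours, used
#'   to derive discharge times in admission mode.
#' @param grid_resolution Named list of per-variable grid steps
#'   (default 1 unit; gap variable 1 day).
#' @param min_stratum_n Pooled fallback threshold for small strata.
#' @return A `reconstructor` object.
#' @export
fit_reconstructor <- function(cohort, schema = cohort$schema,
                              aggregation_map = NULL,
                              joint_pair = NULL,
                              static_strata = "gender",
                              visit_strata = "event_type",
                              los_field = NULL,
                              grid_resolution = list(),
                              min_stratum_n = 30L) {
  vis_cont <- schema_continuous_fields(schema, "visit")
  if (is.null(joint_pair) &&
      all(c("los_total", "los_treatment") %in% vis_cont))
    joint_pair <- c("los_total", "los_treatment")
  if (is.null(los_field) && "los_total" %in% vis_cont)
    los_field <- "los_total"
  res_of <- function(f, default = 1) grid_resolution[[f]] %||% default
  sstrat <- if (!is.null(static_strata) &&
                static_strata %in% names(cohort$patients))
    as.character(cohort$patients[[static_strata]]) else NULL
  vstrat <- if (!is.null(visit_strata) &&
                visit_strata %in% names(cohort$visits))
    as.character(cohort$visits[[visit_strata]]) else NULL

  static_grids <- list()
  for (f in schema_continuous_fields(schema, "static")) {
    static_grids[[f]] <- fit_marginal_kde(cohort$patients[[f]], sstrat,
                                          grid_resolution = res_of(f),
                                          min_stratum_n = min_stratum_n,
                                          variable = f)
  }
  visit_grids <- list()
  for (f in vis_cont) {
    visit_grids[[f]] <- fit_marginal_kde(cohort$visits[[f]], vstrat,
                                         grid_resolution = res_of(f),
                                         min_stratum_n = min_stratum_n,
                                         variable = f)
  }
  joint_grid <- NULL
  if (!is.null(joint_pair)) {
    stopifnot(all(joint_pair %in% vis_cont))
    joint_grid <- fit_joint_kde(cohort$visits[[joint_pair[1]]],
                                cohort$visits[[joint_pair[2]]],
                                grid_resolution_x = res_of(joint_pair[1]),
                                grid_resolution_y = res_of(joint_pair[2]),
                                variables = joint_pair)
  }
  gaps <- compute_gaps(dplyr::arrange(cohort$visits, .data$patient_id,
                                      .data$start_time), schema$gap_mode)
  gap_grid <- fit_marginal_kde(gaps, NULL,
                               grid_resolution = res_of(schema$gap_field),
                               min_stratum_n = min_stratum_n,
                               variable = schema$gap_field)
  structure(list(schema = schema,
                 static_grids = static_grids,
                 visit_grids = visit_grids,
                 joint_grid = joint_grid,
                 joint_pair = joint_pair,
                 gap_grid = gap_grid,
                 calendar = fit_calendar_maps(cohort, schema,
                                              min_stratum_n = min_stratum_n),
                 aggregation_map = aggregation_map,
                 static_strata = static_strata,
                 visit_strata = visit_strata,
                 los_field = los_field,
                 version = 1L),
            class = "reconstructor")
}

#' @export
print.reconstructor <- function(x, ...) {
  cat("<reconstructor> ", length(x$static_grids), " static + ",
      length(x$visit_grids), " visit KDE grids",
      if (!is.null(x$joint_grid)) paste0(", joint pair (",
                                         paste(x$joint_pair, collapse = ", "),
                                         ")"),
      ", calendar window ", format(x$calendar$monday0), " +",
      x$calendar$n_weeks, "w\n", sep = "")
  invisible(x)
}

#' Serialize / restore fitted reconstruction state
#'
#' The sidecar file written at fit time and required at generation time;
#' a versioned header guards against format drift.
#' @param reconstructor A [fit_reconstructor()] result.
#' @param path File path.
#' @return `path` (write) or the restored `reconstructor` (read).
#' @export
write_reconstructor <- function(reconstructor, path) {
  saveRDS(list(format = "synthehr-reconstructor", version = 1L,
               payload = reconstructor), path)
  invisible(path)
}

#' @rdname write_reconstructor
#' @export
read_reconstructor <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "synthehr-reconstructor"))
    stop("not a reconstructor file: ", path)
  if (obj$version > 1L) stop("unsupported reconstructor version ", obj$version)
  obj$payload
}

# grouped two-stage sampling: one call per (band, stratum) group
sample_banded <- function(band_idx, edges, kde_grid, strata = NULL) {
  n <- length(band_idx)
  out <- rep(NA_real_, n)
  ok <- !is.na(band_idx)
  if (!any(ok)) return(out)
  strata <- if (is.null(strata)) rep("(pooled)", n) else as.character(strata)
  key <- paste(band_idx, strata)
  for (k in unique(key[ok])) {
    idx <- which(ok & key == k)
    b <- band_idx[idx[1]]
    out[idx] <- as.numeric(sample_within_band(c(edges[b], edges[b + 1]),
                                              kde_grid,
                                              stratum = strata[idx[1]],
                                              n = length(idx)))
  }
  out
}

sample_banded_joint <- function(bx, by, edges_x, edges_y, joint_grid) {
  n <- length(bx)
  out_x <- rep(NA_real_, n)
  out_y <- rep(NA_real_, n)
  ok <- !is.na(bx) & !is.na(by)
  key <- paste(bx, by)
  for (k in unique(key[ok])) {
    idx <- which(ok & key == k)
    xb <- c(edges_x[bx[idx[1]]], edges_x[bx[idx[1]] + 1])
    yb <- c(edges_y[by[idx[1]]], edges_y[by[idx[1]] + 1])
    s <- sample_joint_within_bands(xb, yb, joint_grid, n = length(idx))
    out_x[idx] <- s$x
    out_y[idx] <- s$y
  }
  list(x = out_x, y = out_y, done = ok)
}

#' Reconstruct a full three-table cohort from tokenized synthetic output
#'
#' Applies the whole post-processing chain: band tokens are inverted to a
#' skeleton, continuous values are drawn by stratified two-stage KDE
#' sampling (the configured correlated pair jointly, unless
#' `joint = FALSE`), calendar timestamps are rebuilt (weekly mode:
#' start-week sampling plus cumulative gap weeks; admission mode: the
#' multi-tier admission/discharge logic), and aggregated diagnosis codes
#' are re-expanded. Missing band tokens stay missing values.
#'
#' @param tokenized A `tokenized_cohort` (typically from
#'   [sample_patients()]).
#' @param reconstructor A [fit_reconstructor()] result.
#' @param rng_seed Integer seed.
#' @param joint Use the joint grid for the configured pair (`FALSE` falls
#'   back to independent marginal reconstruction, mainly for comparison).
#' @return An [ehr_cohort()] in the same layout as the training data.
#' @export
reconstruct_cohort <- function(tokenized, reconstructor, rng_seed = 1L,
                               joint = TRUE) {
  rec <- reconstructor
  schema <- rec$schema
  set.seed(rng_seed)
  skel <- detokenize_structure(tokenized, schema)
  patients <- skel$patients
  visits <- skel$visits

  sstrat <- if (!is.null(rec$static_strata) &&
                rec$static_strata %in% names(patients))
    patients[[rec$static_strata]] else NULL
  for (f in names(rec$static_grids)) {
    bcol <- paste0(f, "_band")
    patients[[f]] <- sample_banded(patients[[bcol]], schema$bands[[f]],
                                   rec$static_grids[[f]], sstrat)
    patients[[bcol]] <- NULL
  }

  vstrat <- if (!is.null(rec$visit_strata) &&
                rec$visit_strata %in% names(visits))
    visits[[rec$visit_strata]] else NULL
  jp <- rec$joint_pair
  if (joint && !is.null(jp) && !is.null(rec$joint_grid)) {
    bx <- visits[[paste0(jp[1], "_band")]]
    by <- visits[[paste0(jp[2], "_band")]]
    js <- sample_banded_joint(bx, by, schema$bands[[jp[1]]],
                              schema$bands[[jp[2]]], rec$joint_grid)
    visits[[jp[1]]] <- js$x
    visits[[jp[2]]] <- js$y
    # one of the pair banded, the other missing: marginal draw
    for (i in 1:2) {
      b <- if (i == 1) bx else by
      left <- !js$done & !is.na(b)
      if (any(left)) {
        f <- jp[i]
        visits[[f]][left] <- sample_banded(b[left], schema$bands[[f]],
                                           rec$visit_grids[[f]],
                                           if (is.null(vstrat)) NULL else
                                             vstrat[left])
      }
    }
  }
  for (f in names(rec$visit_grids)) {
    if (joint && !is.null(jp) && f %in% jp && !is.null(rec$joint_grid)) next
    bcol <- paste0(f, "_band")
    visits[[f]] <- sample_banded(visits[[bcol]], schema$bands[[f]],
                                 rec$visit_grids[[f]], vstrat)
  }
  for (f in c(names(rec$visit_grids)))
    visits[[paste0(f, "_band")]] <- NULL

  gap_days <- sample_banded(visits$gap_band, schema$gap_bands, rec$gap_grid)
  visits$gap_band <- NULL
  visits <- date_visits(visits, gap_days, rec)

  # diagnosis re-expansion, stratified by the static stratum (e.g. gender)
  dx <- skel$diagnoses
  if (nrow(dx) > 0 && !is.null(rec$aggregation_map)) {
    strat <- if (!is.null(sstrat))
      as.character(sstrat)[match(dx$patient_id, patients$patient_id)] else
        "(all)"
    dx$code <- expand_codes(dx$code, strat, rec$aggregation_map)
  }
  out <- ehr_cohort(patients, visits, dx, schema)
  attr(out, "reconstruction_flags") <- attr(visits, "n_clamped")
  out
}

date_visits <- function(visits, gap_days, rec) {
  schema <- rec$schema
  cal <- rec$calendar
  if (schema$timestamp_mode == "weekly") {
    visits$gap_weeks <- ifelse(is.na(gap_days), NA_integer_,
                               as.integer(round_half_up(gap_days / 7)))
    visits <- reconstruct_visit_dates(visits, cal)
    visits$start_time <- as.POSIXct(visits$start_date, tz = "UTC")
    visits$end_time <- as.POSIXct(NA)
    if (!is.null(rec$los_field) && rec$los_field %in% names(visits)) {
      los <- visits[[rec$los_field]]
      has <- !is.na(los)
      visits$end_time[has] <- visits$start_time[has] + los[has] * 3600
    }
    visits$gap_weeks <- NULL
    visits$week <- NULL; visits$dow <- NULL; visits$start_date <- NULL
    visits$clamped <- NULL
    return(visits)
  }
  # admission mode: first admission from the start-week path, later ones
  # through the tier logic, discharge from LOS.
  visits <- dplyr::arrange(visits, .data$patient_id, .data$visit_seq)
  first <- visits$visit_seq == 1
  f1 <- visits[first, c("patient_id", "visit_seq")]
  counts <- table(visits$patient_id)
  f1$gap_weeks <- NA_integer_
  # start week stratified by the patient's total visit count
  tmp <- visits[, c("patient_id", "visit_seq")]
  tmp$gap_weeks <- 0L
  dated1 <- reconstruct_visit_dates(
    dplyr::mutate(tmp, gap_weeks = ifelse(.data$visit_seq == 1, NA, 0L)), cal)
  d1 <- dated1$start_date[dated1$visit_seq == 1]
  pid1 <- dated1$patient_id[dated1$visit_seq == 1]
  hour1 <- sample.int(24, length(d1), replace = TRUE,
                      prob = cal$start_hour_probs) - 1L
  adm1 <- as.POSIXct(d1, tz = "UTC") + hour1 * 3600

  los <- if (!is.null(rec$los_field) && rec$los_field %in% names(visits))
    visits[[rec$los_field]] else rep(NA_real_, nrow(visits))
  start_time <- as.POSIXct(rep(NA_real_, nrow(visits)),
                           origin = "1970-01-01", tz = "UTC")
  end_time <- start_time
  idx1 <- which(first)
  start_time[idx1] <- adm1[match(visits$patient_id[idx1], pid1)]
  end_time[idx1] <- derive_discharge(start_time[idx1], los[idx1],
                                     calendar_maps = cal)
  max_seq <- max(visits$visit_seq)
  if (max_seq > 1) {
    for (k in 2:max_seq) {
      cur <- which(visits$visit_seq == k)
      if (length(cur) == 0) break
      prev <- cur - 1L   # visits sorted by patient, seq
      prev_ref <- end_time[prev]
      miss <- is.na(prev_ref)
      prev_ref[miss] <- start_time[prev][miss]
      gd <- gap_days[cur]
      gd[is.na(gd)] <- 0
      start_time[cur] <- derive_next_admission(prev_ref, gd,
                                               calendar_maps = cal)
      end_time[cur] <- derive_discharge(start_time[cur], los[cur],
                                        calendar_maps = cal)
    }
  }
  visits$start_time <- start_time
  visits$end_time <- end_time
  # ordering repair: overlap intervals may invert start order
  visits <- dplyr::arrange(visits, .data$patient_id, .data$start_time,
                           .data$visit_seq)
  visits <- dplyr::mutate(dplyr::group_by(visits, .data$patient_id),
                          visit_seq = dplyr::row_number())
  dplyr::ungroup(visits)
}
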