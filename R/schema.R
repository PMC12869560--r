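#' Declare the structure of a longitudinal cohort
#'
#' A cohort schema describes the three-table layout (patients, visits,
#' diagnoses) that the whole pipeline operates on: which static patient
#' fields exist and of what kind, which per-visit fields exist, the band
#' edges used to discretise continuous variables into tokens, the diagnosis
#' code vocabulary, the inter-visit gap variable, and the visit cap.
#'
#' Field kinds are `"categorical"` (a fixed set of levels, one token per
#' level), `"continuous"` (discretised into bands, one token per band) and,
#' for static fields only, `"label"` (a binary condition flag usable for
#' conditional generation). Band edges may be left `NULL` and filled later
#' from a training split with [fit_bands()] (per-variable quantile bands).
#'
#' @param static_fields Named character vector of kinds for patient-level
#'   fields, e.g. `c(gender = "categorical", age = "continuous",
#'   diabetes = "label")`.
#' @param visit_fields Named character vector of kinds for visit-level
#'   fields (excluding timestamps, which are handled by the gap variable and
#'   timestamp reconstruction).
#' @param levels Named list of level vectors for every categorical field.
#' @param bands Named list of numeric band-edge vectors (strictly
#'   increasing; bands are left-closed `[e_i, e_{i+1})`) for continuous
#'   fields. Entries may be `NULL` to be fitted from data.
#' @param code_systems Named list of code vocabularies (character vectors),
#'   e.g. `list(diagnosis = c("J45.0", ...))`.
#' @param gap_field Name of the inter-visit interval variable (in days).
#' @param gap_bands Band edges for the gap variable. The default is a
#'   hybrid grid: one dedicated negative/overlap band, per-day bands up to
#'   7 days, then per-week bands, matching the tiers used by timestamp
#'   reconstruction.
#' @param gap_mode `"start"`: gap is days between consecutive visit start
#'   times (never negative); `"discharge"`: days between the previous
#'   visit's end time and the next start (small negative values encode
#'   overlapping episodes).
#' @param max_visits Visit cap per patient; visits beyond it are dropped
#'   (earliest `max_visits` visits are kept).
#' @param n_bands Default number of quantile bands used by [fit_bands()].
#' @param timestamp_mode `"weekly"` for study-style cohorts dated through
#'   start-week sampling plus cumulative week gaps; `"admission"` for
#'   admission/discharge records dated through the multi-tier
#'   admission/discharge logic.
#' @param study_start,study_end Calendar window (`Date`) for the timestamp
#'   lookup tables; weeks are indexed from the Monday of `study_start`'s
#'   week.
#' @return An object of class `cohort_schema`.
#' @export
cohort_schema <- function(static_fields,
                          visit_fields,
                          levels = list(),
                          bands = list(),
                          code_systems = list(),
                          gap_field = "gap_days",
                          gap_bands = default_gap_bands(),
                          gap_mode = c("discharge", "start"),
                          max_visits = 10L,
                          n_bands = 20L,
                          timestamp_mode = c("admission", "weekly"),
                          study_start = as.Date("2019-01-07"),
                          study_end = as.Date("2020-12-31")) {
  gap_mode <- match.arg(gap_mode)
  timestamp_mode <- match.arg(timestamp_mode)
  stopifnot(max_visits >= 1, n_bands >= 2)
  schema <- structure(list(
    static_fields = static_fields,
    visit_fields = visit_fields,
    levels = levels,
    bands = bands,
    code_systems = code_systems,
    gap_field = gap_field,
    gap_bands = gap_bands,
    gap_mode = gap_mode,
    max_visits = as.integer(max_visits),
    n_bands = as.integer(n_bands),
    timestamp_mode = timestamp_mode,
    study_start = study_start,
    study_end = study_end
  ), class = "cohort_schema")
  validate_schema(schema)
  schema
}

#' Default hybrid band grid for the inter-visit gap variable (days)
#'
#' One negative/overlap band, daily bands to one week, weekly bands to two
#' years. The grid mirrors the tier boundaries of timestamp reconstruction.
#' @param max_days Upper edge of the last band.
#' @return Numeric vector of band edges.
#' @export
default_gap_bands <- function(max_days = 735) {
  c(-28, 0:7, seq(14, max_days, by = 7))
}

validate_schema <- function(schema) {
  kinds_s <- unname(schema$static_fields)
  kinds_v <- unname(schema$visit_fields)
  if (!all(kinds_s %in% c("categorical", "continuous", "label")))
    stop("static field kinds must be categorical, continuous or label")
  if (!all(kinds_v %in% c("categorical", "continuous")))
    stop("visit field kinds must be categorical or continuous")
  cats <- c(names(schema$static_fields)[kinds_s == "categorical"],
            names(schema$visit_fields)[kinds_v == "categorical"])
  for (f in cats) {
    if (is.null(schema$levels[[f]]))
      stop("categorical field '", f, "' has no declared levels")
    if (anyDuplicated(schema$levels[[f]]))
      stop("duplicate levels for field '", f, "'")
  }
  for (f in names(schema$bands)) {
    e <- schema$bands[[f]]
    if (!is.null(e) && any(diff(e) <= 0))
      stop("band edges for '", f, "' must be strictly increasing")
  }
  if (any(diff(schema$gap_bands) <= 0))
    stop("gap band edges must be strictly increasing")
  for (s in names(schema$code_systems)) {
    if (anyDuplicated(schema$code_systems[[s]]))
      stop("duplicate codes in code system '", s, "'")
  }
  if (schema$study_end <= schema$study_start)
    stop("study_end must be after study_start")
  invisible(schema)
}

schema_continuous_fields <- function(schema, which = c("static", "visit")) {
  which <- match.arg(which)
  ff <- if (which == "static") schema$static_fields else schema$visit_fields
  names(ff)[unname(ff) == "continuous"]
}

schema_categorical_fields <- function(schema, which = c("static", "visit")) {
  which <- match.arg(which)
  ff <- if (which == "static") schema$static_fields else schema$visit_fields
  names(ff)[unname(ff) == "categorical"]
}

schema_label_fields <- function(schema) {
  names(schema$static_fields)[unname(schema$static_fields) == "label"]
}

#' Fit quantile band edges for continuous fields from a training cohort
#'
#' Continuous fields whose band edges are not declared in the schema get
#' per-variable quantile bands (equal-mass on the training data, default
#' `schema$n_bands`), so that per-band probability mass is bounded. Declared
#' edges are left untouched. The gap variable keeps its hybrid grid.
#'
#' @param schema A [cohort_schema()].
#' @param cohort An [ehr_cohort()] (typically the training split).
#' @param n_bands Number of quantile bands; defaults to `schema$n_bands`.
#' @return The schema with all band edges filled in.
#' @export
fit_bands <- function(schema, cohort, n_bands = NULL) {
  n_bands <- n_bands %||% schema$n_bands
  fill <- function(values, name) {
    v <- values[is.finite(values)]
    if (length(v) < 2) stop("cannot fit bands for '", name, "': no data")
    qs <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bands + 1),
                                 names = FALSE, type = 7))
    if (length(qs) < 2) qs <- c(qs, qs + 1)
    # widen outer edges slightly so observed extremes fall inside
    qs[1] <- qs[1] - 1e-9
    qs[length(qs)] <- qs[length(qs)] + max(1e-9, 1e-9 * abs(qs[length(qs)]))
    qs
  }
  for (f in schema_continuous_fields(schema, "static")) {
    if (is.null(schema$bands[[f]]))
      schema$bands[[f]] <- fill(cohort$patients[[f]], f)
  }
  for (f in schema_continuous_fields(schema, "visit")) {
    if (is.null(schema$bands[[f]]))
      schema$bands[[f]] <- fill(cohort$visits[[f]], f)
  }
  validate_schema(schema)
  schema
}

# Left-closed band lookup with clamping; returns list(idx, n_clamped).
band_lookup <- function(values, edges) {
  idx <- findInterval(values, edges, rightmost.closed = FALSE, left.open = FALSE)
  clamp_lo <- !is.na(values) & idx == 0
  clamp_hi <- !is.na(values) & idx >= length(edges)
  idx[clamp_lo] <- 1L
  idx[clamp_hi] <- length(edges) - 1L
  idx[is.na(values)] <- NA_integer_
  list(idx = idx, n_clamped = sum(clamp_lo) + sum(clamp_hi))
}
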