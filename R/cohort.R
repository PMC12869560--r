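#' Construct a longitudinal cohort from three linked tables
#'
#' The canonical container used throughout the package: a list of three
#' tibbles sharing `patient_id` keys. `patients` holds one row per patient
#' with the static fields, `visits` one row per encounter (with
#' `visit_id`, `start_time`, optionally `end_time`, `event_type` and any
#' visit-level variables), and `diagnoses` one row per (visit, code).
#'
#' @param patients,visits,diagnoses Data frames.
#' @param schema Optional [cohort_schema()] carried along for convenience.
#' @return An object of class `ehr_cohort`.
#' @export
ehr_cohort <- function(patients, visits, diagnoses, schema = NULL) {
  structure(list(
    patients = tibble::as_tibble(patients),
    visits = tibble::as_tibble(visits),
    diagnoses = tibble::as_tibble(diagnoses),
    schema = schema
  ), class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("<ehr_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$visits), " visits, ", nrow(x$diagnoses), " diagnosis rows\n",
      sep = "")
  invisible(x)
}

n_patients <- function(cohort) nrow(cohort$patients)

#' Load, link and order a cohort from raw tables
#'
#' Groups visit rows per patient, sorts them chronologically by start time,
#' drops visits beyond `schema$max_visits` (keeping the earliest), skips
#' orphan visit/diagnosis rows whose `patient_id` (or visit) is unknown, and
#' reports unparseable timestamp rows. Timestamps are parsed as ISO-8601.
#'
#' @param patients_table,visits_table,diagnoses_table Data frames or paths
#'   to delimited text files (comma- or tab-separated, header row).
#' @param schema A [cohort_schema()].
#' @return An [ehr_cohort()]; the load report (orphans skipped, rows
#'   dropped by the visit cap, unparseable timestamps) is attached as
#'   attribute `"load_report"`.
#' @export
load_cohort <- function(patients_table, visits_table, diagnoses_table, schema) {
  patients <- read_table_any(patients_table)
  visits <- read_table_any(visits_table)
  diagnoses <- read_table_any(diagnoses_table)
  for (tb in list(patients, visits, diagnoses)) {
    if (!"patient_id" %in% names(tb)) stop("missing key column 'patient_id'")
  }
  if (!all(c("visit_id", "start_time") %in% names(visits)))
    stop("visits table must have 'visit_id' and 'start_time' columns")

  patients$patient_id <- as.character(patients$patient_id)
  visits$patient_id <- as.character(visits$patient_id)
  diagnoses$patient_id <- as.character(diagnoses$patient_id)

  report <- list(orphan_visits = 0L, orphan_diagnoses = 0L,
                 unparseable_times = 0L, capped_visits = 0L)

  visits$start_time <- parse_time(visits$start_time)
  if ("end_time" %in% names(visits)) {
    visits$end_time <- parse_time(visits$end_time)
  } else {
    visits$end_time <- as.POSIXct(NA)
  }
  bad <- is.na(visits$start_time)
  report$unparseable_times <- sum(bad)
  if (any(bad)) {
    warning(sum(bad), " visit rows with unparseable start_time skipped")
    visits <- visits[!bad, , drop = FALSE]
  }

  orphan <- !visits$patient_id %in% patients$patient_id
  report$orphan_visits <- sum(orphan)
  if (any(orphan)) {
    warning(sum(orphan), " orphan visit rows skipped")
    visits <- visits[!orphan, , drop = FALSE]
  }

  visits <- dplyr::arrange(visits, .data$patient_id, .data$start_time)
  visits <- dplyr::group_by(visits, .data$patient_id)
  visits <- dplyr::mutate(visits, .rank = dplyr::row_number())
  visits <- dplyr::ungroup(visits)
  report$capped_visits <- sum(visits$.rank > schema$max_visits)
  visits <- dplyr::filter(visits, .data$.rank <= schema$max_visits)
  visits$.rank <- NULL

  key <- paste(visits$patient_id, visits$visit_id)
  dkey <- paste(diagnoses$patient_id, diagnoses$visit_id)
  orph_dx <- !dkey %in% key
  report$orphan_diagnoses <- sum(orph_dx)
  if (any(orph_dx)) diagnoses <- diagnoses[!orph_dx, , drop = FALSE]

  out <- ehr_cohort(patients, visits, diagnoses, schema)
  attr(out, "load_report") <- report
  out
}

read_table_any <- function(x) {
  if (is.character(x) && length(x) == 1) {
    sep <- if (grepl("\\.tsv$|\\.txt$", x)) "\t" else ","
    tibble::as_tibble(utils::read.table(x, header = TRUE, sep = sep,
                                        stringsAsFactors = FALSE))
  } else {
    tibble::as_tibble(x)
  }
}

parse_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  if (inherits(x, "Date")) return(as.POSIXct(x, tz = "UTC"))
  suppressWarnings(lubridate::ymd_hms(as.character(x), tz = "UTC",
                                      truncated = 3))
}

#' Write a cohort back to the three-table delimited layout
#'
#' @param cohort An [ehr_cohort()].
#' @param dir Output directory; `patients.csv`, `visits.csv` and
#'   `diagnoses.csv` are written there with ISO-8601 timestamps.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- cohort$visits
  v$start_time <- format(v$start_time, "%Y-%m-%dT%H:%M:%S")
  if ("end_time" %in% names(v))
    v$end_time <- ifelse(is.na(v$end_time), "",
                         format(v$end_time, "%Y-%m-%dT%H:%M:%S"))
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(v, file.path(dir, "visits.csv"), row.names = FALSE)
  utils::write.csv(cohort$diagnoses, file.path(dir, "diagnoses.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory holding `patients.csv`, `visits.csv`,
#'   `diagnoses.csv`.
#' @param schema Optional [cohort_schema()] used to order and cap visits.
#' @return An [ehr_cohort()].
#' @export
read_cohort <- function(dir, schema = NULL) {
  p <- file.path(dir, "patients.csv")
  v <- file.path(dir, "visits.csv")
  d <- file.path(dir, "diagnoses.csv")
  if (is.null(schema)) {
    out <- ehr_cohort(read_table_any(p), read_table_any(v), read_table_any(d))
    out$visits$start_time <- parse_time(out$visits$start_time)
    if ("end_time" %in% names(out$visits))
      out$visits$end_time <- parse_time(out$visits$end_time)
    out
  } else {
    load_cohort(p, v, d, schema)
  }
}

#' Deterministic patient-level train/validation/test split
#'
#' Partitions patients using a floor-then-distribute rule: each part gets
#' `floor(fraction * n)` patients and the remainder is assigned one by one
#' to the parts with the largest fractional remainders (ties resolved in
#' part order). The partition is exhaustive, disjoint and reproducible for
#' a given seed.
#'
#' @param cohort An [ehr_cohort()] or [discretize()] output.
#' @param fractions Positive fractions summing to 1; names become the part
#'   names (default `train`/`validation`/`test`).
#' @param seed Integer seed controlling the patient shuffle.
#' @return Named list of cohorts of the same class as the input.
#' @export
split_cohort <- function(cohort, fractions = c(train = 0.8, validation = 0.1,
                                               test = 0.1), seed = 1L) {
  stopifnot(all(fractions > 0), abs(sum(fractions) - 1) < 1e-8)
  if (is.null(names(fractions)))
    names(fractions) <- paste0("part", seq_along(fractions))
  ids <- cohort_patient_ids(cohort)
  n <- length(ids)
  if (n < length(fractions)) stop("fewer patients than partitions")
  sizes <- floor(fractions * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac_rem <- fractions * n - sizes
    give <- order(-frac_rem, seq_along(fractions))[seq_len(rem)]
    sizes[give] <- sizes[give] + 1
  }
  ord <- withr::with_seed(seed, sample(ids))
  cuts <- cumsum(sizes)
  starts <- c(1, utils::head(cuts, -1) + 1)
  parts <- lapply(seq_along(fractions), function(i) {
    subset_patients(cohort, ord[starts[i]:cuts[i]])
  })
  names(parts) <- names(fractions)
  parts
}

cohort_patient_ids <- function(cohort) {
  if (inherits(cohort, "ehr_cohort")) as.character(cohort$patients$patient_id)
  else if (inherits(cohort, "tokenized_cohort")) names(cohort$records)
  else stop("unsupported cohort class")
}

subset_patients <- function(cohort, ids) {
  if (inherits(cohort, "ehr_cohort")) {
    out <- ehr_cohort(
      cohort$patients[match(ids, cohort$patients$patient_id), , drop = FALSE],
      dplyr::filter(cohort$visits, .data$patient_id %in% ids),
      dplyr::filter(cohort$diagnoses, .data$patient_id %in% ids),
      cohort$schema
    )
    out
  } else if (inherits(cohort, "tokenized_cohort")) {
    out <- cohort
    out$records <- cohort$records[ids]
    out
  } else stop("unsupported cohort class")
}
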