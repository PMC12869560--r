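#' Aggregate rare diagnosis codes to shorter prefixes
#'
#' Codes occurring fewer than `min_count` times cohort-wide are replaced by
#' a prefix: candidate prefix lengths are tried longest first and the first
#' prefix whose pooled rare-code count reaches `min_count` is used; if none
#' does, the shortest candidate is used as a fallback. Codes at or above the
#' threshold are left untouched. The empirical distribution of full codes
#' within each aggregated category, stratified by a patient-level variable
#' (default gender), is recorded so that [expand_codes()] can re-expand
#' aggregated codes in synthetic output.
#'
#' @param cohort An [ehr_cohort()].
#' @param min_count Occurrence threshold below which a code is aggregated.
#' @param prefix_lengths Candidate prefix lengths, descending.
#' @param stratify_by Patient column used for the empirical re-expansion
#'   tables (`NULL` for pooled tables only).
#' @return A list with elements `cohort` (diagnosis codes rewritten) and
#'   `map` (a `code_aggregation_map`).
#' @export
aggregate_codes <- function(cohort, min_count = 50L, prefix_lengths = c(3L, 2L),
                            stratify_by = "gender") {
  stopifnot(min_count >= 1, length(prefix_lengths) >= 1)
  prefix_lengths <- sort(as.integer(prefix_lengths), decreasing = TRUE)
  dx <- cohort$diagnoses
  counts <- table(dx$code)
  rare <- names(counts)[counts < min_count]
  forward <- stats::setNames(names(counts), names(counts))
  if (length(rare) > 0) {
    rare_counts <- counts[rare]
    for (code in rare) {
      assigned <- NA_character_
      for (len in prefix_lengths) {
        pfx <- substr(code, 1, len)
        pooled <- sum(rare_counts[substr(rare, 1, len) == pfx])
        if (pooled >= min_count) { assigned <- pfx; break }
      }
      if (is.na(assigned))
        assigned <- substr(code, 1, min(prefix_lengths))
      forward[code] <- assigned
    }
  }
  # empirical per-stratum tables over full codes for each aggregated category
  agg_targets <- unique(forward[forward != names(forward)])
  empirical <- NULL
  if (length(agg_targets) > 0) {
    strat <- if (!is.null(stratify_by) &&
                 stratify_by %in% names(cohort$patients)) {
      cohort$patients[[stratify_by]][match(dx$patient_id,
                                           cohort$patients$patient_id)]
    } else rep("(all)", nrow(dx))
    keep <- forward[dx$code] %in% agg_targets
    if (any(keep)) {
      emp <- tibble::tibble(
        aggregated = unname(forward[dx$code[keep]]),
        stratum = as.character(strat[keep]),
        code = dx$code[keep]
      )
      empirical <- dplyr::count(emp, .data$aggregated, .data$stratum,
                                .data$code, name = "n")
      empirical <- dplyr::mutate(
        dplyr::group_by(empirical, .data$aggregated, .data$stratum),
        prob = .data$n / sum(.data$n))
      empirical <- dplyr::ungroup(empirical)
      pooled <- dplyr::count(emp, .data$aggregated, .data$code, name = "n")
      pooled$stratum <- "(pooled)"
      pooled <- dplyr::mutate(dplyr::group_by(pooled, .data$aggregated),
                              prob = .data$n / sum(.data$n))
      pooled <- dplyr::ungroup(pooled)
      empirical <- dplyr::bind_rows(empirical,
                                    pooled[, names(empirical)])
    }
  }
  map <- structure(list(forward = forward, empirical = empirical,
                        stratify_by = stratify_by,
                        min_count = min_count,
                        prefix_lengths = prefix_lengths),
                   class = "code_aggregation_map")
  cohort$diagnoses$code <- unname(forward[cohort$diagnoses$code])
  # schema vocabulary follows the aggregation
  if (!is.null(cohort$schema) && length(cohort$schema$code_systems) > 0) {
    for (s in names(cohort$schema$code_systems)) {
      v <- cohort$schema$code_systems[[s]]
      mapped <- ifelse(v %in% names(forward), unname(forward[v]), v)
      cohort$schema$code_systems[[s]] <- unique(mapped)
    }
  }
  list(cohort = cohort, map = map)
}

#' Re-expand aggregated diagnosis codes to full-resolution codes
#'
#' Each aggregated category is mapped back to a specific full code by
#' sampling from the empirical distribution of codes within that category,
#' stratified by the variable recorded at aggregation time (the pooled
#' table is used for unseen strata). Codes that were never aggregated pass
#' through unchanged; unknown aggregated codes pass through with a warning.
#'
#' @param codes Character vector of (possibly aggregated) codes.
#' @param stratum Character vector (length 1 or `length(codes)`) giving the
#'   stratum of each draw, e.g. patient gender.
#' @param map A `code_aggregation_map` from [aggregate_codes()].
#' @return Character vector of full-resolution codes.
#' @export
expand_codes <- function(codes, stratum, map) {
  if (is.null(map$empirical)) return(codes)
  stratum <- rep_len(as.character(stratum), length(codes))
  emp <- map$empirical
  agg_set <- unique(emp$aggregated)
  out <- codes
  is_agg <- codes %in% agg_set
  full_set <- names(map$forward)
  unknown <- !is_agg & !codes %in% full_set & !codes %in% unname(map$forward)
  if (any(unknown))
    warning(sum(unknown), " unknown codes passed through unexpanded")
  if (!any(is_agg)) return(out)
  key <- paste(codes, stratum, sep = "\r")
  have <- paste(emp$aggregated, emp$stratum, sep = "\r")
  use_pooled <- is_agg & !key %in% have
  key[use_pooled] <- paste(codes[use_pooled], "(pooled)", sep = "\r")
  idx_by_key <- split(which(is_agg), key[is_agg])
  tab_by_key <- split(seq_len(nrow(emp)), have)
  for (k in names(idx_by_key)) {
    rows <- tab_by_key[[k]]
    if (is.null(rows)) next
    ii <- idx_by_key[[k]]
    out[ii] <- sample(emp$code[rows], length(ii), replace = TRUE,
                      prob = emp$prob[rows])
  }
  out
}
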