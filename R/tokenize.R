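# Token representation of a cohort.
#
# Vocabulary layout: special tokens first (<start>, <eov>, <eor>), then
# static tokens (categorical levels, continuous bands, binary labels), then
# visit tokens (categorical levels, continuous bands, the gap bands) and
# finally the code tokens. Missing continuous values carry no band token
# (missingness is represented by absence so the engine can learn it).

TOK_START <- "<start>"
TOK_EOV <- "<eov>"
TOK_EOR <- "<eor>"

build_vocab <- function(schema) {
  rows <- list(
    tibble::tibble(token = c(TOK_START, TOK_EOV, TOK_EOR), role = "special",
                   field = NA_character_, system = NA_character_,
                   level = NA_character_, band = NA_integer_,
                   lo = NA_real_, hi = NA_real_)
  )
  band_rows <- function(field, edges, role) {
    nb <- length(edges) - 1
    tibble::tibble(
      token = sprintf("%s:%s=%02d", substr(role, 1, 1), field, seq_len(nb)),
      role = role, field = field, system = NA_character_,
      level = NA_character_, band = seq_len(nb),
      lo = edges[-length(edges)], hi = edges[-1]
    )
  }
  for (f in names(schema$static_fields)) {
    kind <- schema$static_fields[[f]]
    rows[[length(rows) + 1]] <- switch(kind,
      categorical = tibble::tibble(
        token = paste0("s:", f, "=", schema$levels[[f]]),
        role = "static_cat", field = f, system = NA_character_,
        level = schema$levels[[f]], band = NA_integer_,
        lo = NA_real_, hi = NA_real_),
      continuous = {
        if (is.null(schema$bands[[f]]))
          stop("no band edges for static field '", f,
               "'; call fit_bands() first")
        band_rows(f, schema$bands[[f]], "static_band")
      },
      label = tibble::tibble(
        token = paste0("l:", f), role = "label", field = f,
        system = NA_character_, level = NA_character_,
        band = NA_integer_, lo = NA_real_, hi = NA_real_)
    )
  }
  for (f in names(schema$visit_fields)) {
    kind <- schema$visit_fields[[f]]
    rows[[length(rows) + 1]] <- switch(kind,
      categorical = tibble::tibble(
        token = paste0("v:", f, "=", schema$levels[[f]]),
        role = "visit_cat", field = f, system = NA_character_,
        level = schema$levels[[f]], band = NA_integer_,
        lo = NA_real_, hi = NA_real_),
      continuous = {
        if (is.null(schema$bands[[f]]))
          stop("no band edges for visit field '", f,
               "'; call fit_bands() first")
        band_rows(f, schema$bands[[f]], "visit_band")
      }
    )
  }
  gap <- band_rows(schema$gap_field, schema$gap_bands, "gap_band")
  gap$token <- sprintf("g:%s=%02d", schema$gap_field, gap$band)
  rows[[length(rows) + 1]] <- gap
  for (s in names(schema$code_systems)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      token = paste0("c:", s, ":", schema$code_systems[[s]]),
      role = "code", field = NA_character_, system = s,
      level = schema$code_systems[[s]], band = NA_integer_,
      lo = NA_real_, hi = NA_real_)
  }
  prov <- dplyr::bind_rows(rows)
  if (anyDuplicated(prov$token)) stop("vocabulary tokens not unique")
  prov$index <- seq_len(nrow(prov))
  prov
}

#' Discretise a cohort into its token representation
#'
#' Continuous variables are mapped to their band token (left-closed bands;
#' out-of-range values are clamped to the outermost band and counted),
#' categorical variables to level tokens, diagnosis codes to code tokens
#' and statics to label/static tokens. The inter-visit gap variable is
#' computed from consecutive timestamps according to `schema$gap_mode`;
#' the first visit carries no gap token. Missing values produce no token.
#'
#' @param cohort An [ehr_cohort()].
#' @param schema A [cohort_schema()] with all band edges present (see
#'   [fit_bands()]).
#' @return A `tokenized_cohort`: vocabulary, token provenance table and
#'   per-patient records of token-index vectors (one static vector plus one
#'   vector per visit). A clamp/warning report is attached as attribute
#'   `"discretize_report"`.
#' @export
discretize <- function(cohort, schema = cohort$schema) {
  if (is.null(schema)) stop("schema required")
  prov <- build_vocab(schema)
  vocab <- prov$token
  tok_index <- stats::setNames(prov$index, prov$token)
  n_clamped <- 0L

  pat <- cohort$patients
  vis <- dplyr::arrange(cohort$visits, .data$patient_id, .data$start_time)

  # static token indices per patient
  static_idx <- vector("list", nrow(pat))
  for (f in names(schema$static_fields)) {
    kind <- schema$static_fields[[f]]
    if (kind == "categorical") {
      toks <- paste0("s:", f, "=", as.character(pat[[f]]))
      ti <- tok_index[toks]
      for (i in which(!is.na(ti))) static_idx[[i]] <- c(static_idx[[i]], ti[[i]])
    } else if (kind == "continuous") {
      bl <- band_lookup(pat[[f]], schema$bands[[f]])
      n_clamped <- n_clamped + bl$n_clamped
      toks <- sprintf("s:%s=%02d", f, bl$idx)
      ti <- tok_index[toks]
      for (i in which(!is.na(bl$idx))) static_idx[[i]] <- c(static_idx[[i]], ti[[i]])
    } else {
      on <- !is.na(pat[[f]]) & (pat[[f]] == 1 | pat[[f]] == TRUE)
      ti <- tok_index[paste0("l:", f)]
      for (i in which(on)) static_idx[[i]] <- c(static_idx[[i]], ti)
    }
  }

  # per-visit token indices
  nv <- nrow(vis)
  visit_tok <- vector("list", nv)
  for (f in names(schema$visit_fields)) {
    kind <- schema$visit_fields[[f]]
    if (kind == "categorical") {
      ti <- tok_index[paste0("v:", f, "=", as.character(vis[[f]]))]
      for (i in which(!is.na(ti))) visit_tok[[i]] <- c(visit_tok[[i]], ti[[i]])
    } else {
      bl <- band_lookup(vis[[f]], schema$bands[[f]])
      n_clamped <- n_clamped + bl$n_clamped
      ti <- tok_index[sprintf("v:%s=%02d", f, bl$idx)]
      for (i in which(!is.na(bl$idx))) visit_tok[[i]] <- c(visit_tok[[i]], ti[[i]])
    }
  }
  # gap variable from consecutive timestamps
  gaps <- compute_gaps(vis, schema$gap_mode)
  gl <- band_lookup(gaps, schema$gap_bands)
  n_clamped <- n_clamped + gl$n_clamped
  gti <- tok_index[sprintf("g:%s=%02d", schema$gap_field, gl$idx)]
  for (i in which(!is.na(gl$idx))) visit_tok[[i]] <- c(visit_tok[[i]], gti[[i]])
  # codes
  if (nrow(cohort$diagnoses) > 0) {
    sysname <- names(schema$code_systems)[1] %||% "diagnosis"
    dsys <- if ("system" %in% names(cohort$diagnoses))
      cohort$diagnoses$system else sysname
    dti <- tok_index[paste0("c:", dsys, ":", cohort$diagnoses$code)]
    vkey <- paste(vis$patient_id, vis$visit_id)
    drow <- match(paste(cohort$diagnoses$patient_id,
                        cohort$diagnoses$visit_id), vkey)
    ok <- !is.na(dti) & !is.na(drow)
    for (i in which(ok)) visit_tok[[drow[i]]] <-
      unique(c(visit_tok[[drow[i]]], dti[[i]]))
  }

  pid <- as.character(pat$patient_id)
  vis_by_pat <- split(seq_len(nv), factor(vis$patient_id, levels = pid))
  records <- lapply(seq_along(pid), function(i) {
    list(static = sort(unname(static_idx[[i]] %||% integer(0))),
         visits = lapply(vis_by_pat[[i]], function(r)
           sort(unname(visit_tok[[r]] %||% integer(0)))))
  })
  names(records) <- pid

  out <- structure(list(vocab = vocab, provenance = prov, records = records,
                        schema = schema), class = "tokenized_cohort")
  attr(out, "discretize_report") <- list(n_clamped = n_clamped)
  if (n_clamped > 0)
    warning(n_clamped, " out-of-range continuous values clamped to outer bands")
  out
}

compute_gaps <- function(vis, gap_mode) {
  n <- nrow(vis)
  gaps <- rep(NA_real_, n)
  if (n == 0) return(gaps)
  same_prev <- c(FALSE, vis$patient_id[-1] == vis$patient_id[-n])
  if (gap_mode == "start") {
    prev_ref <- c(as.POSIXct(NA), vis$start_time[-n])
  } else {
    ref <- vis$end_time
    ref[is.na(ref)] <- vis$start_time[is.na(ref)]
    prev_ref <- c(as.POSIXct(NA), ref[-n])
  }
  idx <- which(same_prev)
  gaps[idx] <- as.numeric(difftime(vis$start_time[idx], prev_ref[idx],
                                   units = "days"))
  gaps
}

#' @export
print.tokenized_cohort <- function(x, ...) {
  cat("<tokenized_cohort> ", length(x$records), " patients, vocabulary size ",
      length(x$vocab), "\n", sep = "")
  invisible(x)
}

#' Invert the token representation into a banded cohort skeleton
#'
#' The inverse mapping applied before reconstruction: continuous fields are
#' returned as band indices (value sampling happens later), timestamps are
#' unset, codes and categorical levels are restored. A visit vector with
#' two active band tokens for one variable is an integrity error naming the
#' variable; zero band tokens mark the variable as missing.
#'
#' @param tokenized A `tokenized_cohort` (from [discretize()] or
#'   [sample_patients()]).
#' @param schema A [cohort_schema()]; defaults to the one carried by
#'   `tokenized`.
#' @return A `cohort_skeleton`: list of tibbles `patients` (static levels
#'   plus `<field>_band` columns), `visits` (per-visit band columns,
#'   `gap_band`, `event ` levels) and `diagnoses`.
#' @export
detokenize_structure <- function(tokenized, schema = tokenized$schema) {
  prov <- tokenized$provenance
  recs <- tokenized$records
  pid <- names(recs)
  one_of_role <- function(idx, role_sel, field = NULL, what = "") {
    sel <- prov$role[idx] %in% role_sel
    if (!is.null(field)) sel <- sel & prov$field[idx] %in% field
    hits <- idx[sel]
    if (length(hits) > 1)
      stop("integrity error: multiple active tokens for ", what)
    if (length(hits) == 0) NA_integer_ else hits
  }
  # patients
  stat_rows <- lapply(seq_along(recs), function(i) {
    idx <- recs[[i]]$static
    row <- list(patient_id = pid[i])
    for (f in names(schema$static_fields)) {
      kind <- schema$static_fields[[f]]
      if (kind == "categorical") {
        hit <- one_of_role(idx, "static_cat", f, paste0("static field ", f))
        row[[f]] <- if (is.na(hit)) NA_character_ else prov$level[hit]
      } else if (kind == "continuous") {
        hit <- one_of_role(idx, "static_band", f, paste0("static field ", f))
        row[[paste0(f, "_band")]] <- if (is.na(hit)) NA_integer_ else prov$band[hit]
      } else {
        lt <- prov$index[prov$role == "label" & prov$field == f]
        row[[f]] <- as.integer(lt %in% idx)
      }
    }
    row
  })
  patients <- dplyr::bind_rows(stat_rows)
  # visits
  vrows <- list()
  drows <- list()
  for (i in seq_along(recs)) {
    vl <- recs[[i]]$visits
    for (k in seq_along(vl)) {
      idx <- vl[[k]]
      row <- list(patient_id = pid[i], visit_id = paste0("v", k),
                  visit_seq = k)
      for (f in names(schema$visit_fields)) {
        kind <- schema$visit_fields[[f]]
        if (kind == "categorical") {
          hit <- one_of_role(idx, "visit_cat", f, paste0("visit field ", f))
          row[[f]] <- if (is.na(hit)) NA_character_ else prov$level[hit]
        } else {
          hit <- one_of_role(idx, "visit_band", f, paste0("visit field ", f))
          row[[paste0(f, "_band")]] <-
            if (is.na(hit)) NA_integer_ else prov$band[hit]
        }
      }
      ghit <- one_of_role(idx, "gap_band", schema$gap_field,
                          paste0("gap field ", schema$gap_field))
      row$gap_band <- if (is.na(ghit)) NA_integer_ else prov$band[ghit]
      vrows[[length(vrows) + 1]] <- row
      codes <- idx[prov$role[idx] == "code"]
      if (length(codes) > 0) {
        drows[[length(drows) + 1]] <- tibble::tibble(
          patient_id = pid[i], visit_id = paste0("v", k),
          system = prov$system[codes], code = prov$level[codes])
      }
    }
  }
  visits <- dplyr::bind_rows(vrows)
  diagnoses <- if (length(drows) > 0) dplyr::bind_rows(drows) else
    tibble::tibble(patient_id = character(), visit_id = character(),
                   system = character(), code = character())
  structure(list(patients = patients, visits = visits, diagnoses = diagnoses,
                 schema = schema), class = "cohort_skeleton")
}
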