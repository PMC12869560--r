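# Constrained, optionally conditional generation from a trained engine.

#' Declare deterministic generation constraints
#'
#' Three rule kinds are supported, applied within a visit while it is being
#' sampled: `forbid-token` (consequent tokens can never activate),
#' `forbid-co-occurrence` (once every token of one side is active, the
#' other side is masked to probability 0) and `require-if` (once all
#' antecedent tokens are active, consequent tokens are forced to
#' probability 1).
#'
#' @param ... Lists with elements `kind`, `antecedent` (character vector of
#'   tokens, may be empty), `consequent` (character vector).
#' @return A `constraint_rules` object.
#' @export
constraint_rules <- function(...) {
  rules <- list(...)
  for (r in rules) {
    if (!r$kind %in% c("forbid-token", "forbid-co-occurrence", "require-if"))
      stop("unknown rule kind: ", r$kind)
    if (length(r$consequent) == 0) stop("rule with empty consequent")
  }
  structure(rules, class = "constraint_rules")
}

resolve_rules <- function(rules, vocab) {
  lapply(rules, function(r) {
    ai <- match(r$antecedent %||% character(0), vocab)
    ci <- match(r$consequent, vocab)
    if (anyNA(ai) || anyNA(ci))
      stop("rule references tokens absent from the vocabulary: ",
           paste(c(r$antecedent, r$consequent)[is.na(c(ai, ci))],
                 collapse = ", "))
    list(kind = r$kind, a = ai, c = ci)
  })
}

#' Apply constraint rules to predicted token probabilities
#'
#' Given the tokens already active in a partially sampled visit, tokens
#' whose activation would violate a rule are forced to probability 0 and
#' tokens required by a satisfied `require-if` antecedent are forced to 1;
#' all other entries are unchanged. A token forced to both 0 and 1 by
#' contradictory rules is an error.
#'
#' @param probabilities Numeric vector over the vocabulary, or a matrix
#'   with one row per partial visit.
#' @param partial_visit Binary vector/matrix of the same shape marking
#'   already-active tokens.
#' @param rules A [constraint_rules()] object.
#' @param vocab Character vocabulary the token names resolve against.
#' @return Modified probabilities, same shape as the input.
#' @export
apply_constraints <- function(probabilities, partial_visit, rules, vocab) {
  vec_in <- is.null(dim(probabilities))
  P <- if (vec_in) matrix(probabilities, nrow = 1) else probabilities
  A <- if (is.null(dim(partial_visit))) matrix(partial_visit, nrow = 1) else
    partial_visit
  rr <- resolve_rules(rules, vocab)
  out <- apply_constraints_idx(P, A != 0, rr)
  if (vec_in) drop(out) else out
}

# internal matrix version with resolved token indices
apply_constraints_idx <- function(P, A, rr) {
  force0 <- matrix(FALSE, nrow(P), ncol(P))
  force1 <- matrix(FALSE, nrow(P), ncol(P))
  all_active <- function(idx) {
    if (length(idx) == 0) return(rep(TRUE, nrow(P)))
    if (length(idx) == 1) return(A[, idx])
    rowSums(A[, idx, drop = FALSE]) == length(idx)
  }
  for (r in rr) {
    if (r$kind == "forbid-token") {
      force0[, r$c] <- TRUE
    } else if (r$kind == "forbid-co-occurrence") {
      hit_a <- all_active(r$a)
      force0[hit_a, r$c] <- TRUE
      hit_c <- all_active(r$c)
      force0[hit_c, r$a] <- TRUE
    } else { # require-if
      hit <- all_active(r$a)
      force1[hit, r$c] <- TRUE
    }
  }
  if (any(force0 & force1))
    stop("contradictory rules: a token is forced to probability 0 and 1")
  P[force0] <- 0
  P[force1] <- 1
  P
}

# Inverse-CDF categorical sampling per row; zero-mass rows -> NA.
sample_categorical_rows <- function(P) {
  tot <- rowSums(P)
  n <- nrow(P)
  out <- rep(NA_integer_, n)
  ok <- tot > 0
  if (any(ok)) {
    u <- stats::runif(n) * tot
    cum <- P
    if (ncol(P) > 1) {
      for (j in 2:ncol(P)) cum[, j] <- cum[, j - 1] + P[, j]
    }
    out[ok] <- rowSums(cum[ok, , drop = FALSE] < u[ok]) + 1L
  }
  out
}

#' Sample synthetic tokenized patients from a trained engine
#'
#' Generation is autoregressive visit-by-visit: the condition-label vector
#' is generated first (with any `condition_labels` clamped active), then
#' the demographic static vector conditioned on the labels, then visits
#' until the end-of-record token fires or the visit cap is reached.
#' Within a visit, banded variables are sampled as grouped categorical
#' draws over their band tokens (with absence representing missingness),
#' codes as independent Bernoulli draws, both after constraint masking via
#' [apply_constraints()] given the tokens already active in the partial
#' visit; a final repair pass enforces `require-if` consequents and
#' re-checks forbid rules to a fixed point.
#'
#' @param model A `generator_model` from [train_engine()].
#' @param n Number of patients to generate.
#' @param rng_seed Integer seed; output is deterministic given the seed.
#' @param rules Optional [constraint_rules()].
#' @param condition_labels Optional character vector of label tokens (e.g.
#'   `"l:diabetes"`) clamped active before visit generation.
#' @param temperature Logit temperature; defaults to the model config.
#' @param chunk_size Patients generated per vectorised batch.
#' @return A `tokenized_cohort` of `n` synthetic patients.
#' @export
sample_patients <- function(model, n, rng_seed = 1L, rules = NULL,
                            condition_labels = NULL, temperature = NULL,
                            chunk_size = 1000L) {
  stopifnot(n >= 1)
  temperature <- temperature %||% model$config$temperature
  prov <- model$provenance
  vocab <- model$vocab
  if (!is.null(condition_labels)) {
    lab_tokens <- prov$token[prov$role == "label"]
    if (!all(condition_labels %in% lab_tokens))
      stop("condition_labels must be label tokens; offending: ",
           paste(setdiff(condition_labels, lab_tokens), collapse = ", "))
  }
  rr <- if (!is.null(rules)) resolve_rules(rules, vocab) else NULL
  set.seed(rng_seed)
  recs <- list()
  remaining <- n
  while (remaining > 0) {
    B <- min(chunk_size, remaining)
    recs <- c(recs, generate_chunk(model, B, rr, condition_labels, temperature))
    remaining <- remaining - B
  }
  names(recs) <- sprintf("synth%06d", seq_len(n))
  structure(list(vocab = vocab, provenance = prov, records = recs,
                 schema = model$schema), class = "tokenized_cohort")
}

generate_chunk <- function(model, B, rr, condition_labels, temperature) {
  prov <- model$provenance
  V <- length(model$vocab)
  S <- model$config$max_sequence_length
  i_start <- prov$index[prov$token == TOK_START]
  i_eov <- prov$index[prov$token == TOK_EOV]
  i_eor <- prov$index[prov$token == TOK_EOR]
  schema <- model$schema

  X <- matrix(0, B * S, V)
  ipos_all <- rep(seq_len(S), B)
  row_at <- function(t) (seq_len(B) - 1L) * S + t
  X[row_at(1L), i_start] <- 1

  probs_at <- function(t) {
    # predicted probabilities for position t+1 given prefix 1..t; only
    # the prefix is run through the network and only position t's rows
    # are projected to logits
    pre <- as.vector(outer(seq_len(t), (seq_len(B) - 1L) * S, "+"))
    fwd <- nn_forward(model$params, X[pre, , drop = FALSE], B, t,
                      logits_rows = seq(t, B * t, by = t))
    1 / (1 + exp(-fwd$logits / temperature))
  }

  # ---- label position (generated first, so statics condition on it) ----
  P <- probs_at(1L)
  lrow <- matrix(0, B, V)
  for (f in schema_label_fields(schema)) {
    col <- prov$index[prov$role == "label" & prov$field == f]
    tok <- prov$token[col]
    if (!is.null(condition_labels) && tok %in% condition_labels) {
      lrow[, col] <- 1
    } else {
      lrow[, col] <- as.numeric(stats::runif(B) < P[, col])
    }
  }
  X[row_at(2L), ] <- lrow

  # ---- demographic/static position ----
  P <- probs_at(2L)
  srow <- matrix(0, B, V)
  for (f in schema_categorical_fields(schema, "static")) {
    cols <- prov$index[prov$role == "static_cat" & prov$field == f]
    pick <- sample_categorical_rows(P[, cols, drop = FALSE])
    pick[is.na(pick)] <- 1L
    srow[cbind(seq_len(B), cols[pick])] <- 1
  }
  for (f in schema_continuous_fields(schema, "static")) {
    cols <- prov$index[prov$role == "static_band" & prov$field == f]
    pres <- stats::runif(B) < pmin(1, rowSums(P[, cols, drop = FALSE]))
    pick <- sample_categorical_rows(P[, cols, drop = FALSE])
    on <- pres & !is.na(pick)
    srow[cbind(which(on), cols[pick[on]])] <- 1
  }
  X[row_at(3L), ] <- srow

  alive <- rep(TRUE, B)
  visit_count <- integer(B)
  max_visits <- S - 4L
  gap_cols <- prov$index[prov$role == "gap_band"]
  code_cols <- prov$index[prov$role == "code"]

  for (vn in seq_len(max_visits)) {
    t <- 3L + vn
    if (!any(alive)) break
    P <- probs_at(t - 1L)
    # termination decision (every record has at least one visit)
    if (vn > 1L) {
      stop_now <- alive & stats::runif(B) < P[, i_eor]
      if (any(stop_now)) {
        X[row_at(t)[stop_now], i_eor] <- 1
        alive[stop_now] <- FALSE
      }
    }
    act <- which(alive)
    if (length(act) == 0) break
    vrow <- matrix(0, length(act), V)
    Pa <- P[act, , drop = FALSE]
    mask_probs <- function(pr) {
      if (is.null(rr)) pr else apply_constraints_idx(pr, vrow != 0, rr)
    }
    for (f in schema_categorical_fields(schema, "visit")) {
      cols <- prov$index[prov$role == "visit_cat" & prov$field == f]
      pm <- mask_probs(Pa)
      pick <- sample_categorical_rows(pm[, cols, drop = FALSE])
      if (anyNA(pick))
        stop("rule set forbids all levels of visit field '", f, "'")
      vrow[cbind(seq_along(act), cols[pick])] <- 1
    }
    for (f in schema_continuous_fields(schema, "visit")) {
      cols <- prov$index[prov$role == "visit_band" & prov$field == f]
      pm <- mask_probs(Pa)
      pres <- stats::runif(length(act)) <
        pmin(1, rowSums(pm[, cols, drop = FALSE]))
      pick <- sample_categorical_rows(pm[, cols, drop = FALSE])
      on <- pres & !is.na(pick)
      vrow[cbind(which(on), cols[pick[on]])] <- 1
    }
    if (vn > 1L) {
      pm <- mask_probs(Pa)
      pick <- sample_categorical_rows(pm[, gap_cols, drop = FALSE])
      if (anyNA(pick))
        stop("rule set forbids all gap bands")
      vrow[cbind(seq_along(act), gap_cols[pick])] <- 1
    }
    if (is.null(rr)) {
      U <- matrix(stats::runif(length(act) * length(code_cols)),
                  length(act), length(code_cols))
      vrow[, code_cols] <- (U < Pa[, code_cols, drop = FALSE]) + 0
    } else {
      for (ci in code_cols) {
        pm <- mask_probs(Pa)
        vrow[, ci] <- as.numeric(stats::runif(length(act)) < pm[, ci])
      }
    }
    vrow[, i_eov] <- 1
    vrow <- repair_visit(vrow, rr)
    X[row_at(t)[act], ] <- vrow
    visit_count[act] <- vn
  }
  # close any records still open
  still <- which(alive)
  if (length(still) > 0) X[row_at(S)[still], i_eor] <- 1

  # assemble records
  lapply(seq_len(B), function(b) {
    k <- visit_count[b]
    rows <- (b - 1L) * S + 3L + seq_len(k)
    list(
      static = sort(c(which(X[(b - 1L) * S + 2L, ] != 0),
                      which(X[(b - 1L) * S + 3L, ] != 0))),
      visits = lapply(rows, function(r) {
        idx <- which(X[r, ] != 0)
        idx[idx != i_eov]
      })
    )
  })
}

# require-if consequents of satisfied antecedents are switched on, then
# forbid rules re-checked; iterated to a fixed point (oscillation = error).
repair_visit <- function(vrow, rr) {
  if (is.null(rr)) return(vrow)
  for (iter in 1:10) {
    before <- vrow
    for (r in rr) {
      if (r$kind == "require-if") {
        hit <- if (length(r$a) == 0) rep(TRUE, nrow(vrow)) else
          rowSums(vrow[, r$a, drop = FALSE] != 0) == length(r$a)
        vrow[hit, r$c] <- 1
      }
    }
    for (r in rr) {
      if (r$kind == "forbid-token") {
        vrow[, r$c] <- 0
      } else if (r$kind == "forbid-co-occurrence") {
        hit_a <- if (length(r$a) == 0) rep(TRUE, nrow(vrow)) else
          rowSums(vrow[, r$a, drop = FALSE] != 0) == length(r$a)
        vrow[hit_a, r$c] <- 0
      }
    }
    if (identical(before, vrow)) return(vrow)
  }
  stop("contradictory rules: constraint repair did not converge")
}
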