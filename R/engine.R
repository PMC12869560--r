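# The autoregressive visit-sequence engine.
#
# Sequence layout (one position per visit, multi-hot vectors):
#   position 1: <start>
#   position 2: condition-label tokens (generated first, so that
#               demographics and visits are conditioned on them)
#   position 3: the remaining static tokens (demographic levels/bands)
#   positions 4..k+3: visit vectors (codes, band tokens, <eov>)
#   position k+4: <eor>
# so max_sequence_length = max_visits + 4. The model predicts position
# t+1's multi-hot vector from positions 1..t through a sigmoid output;
# training minimises binary cross-entropy computed from raw logits.

#' Engine configuration
#'
#' Desk-scale defaults (2 layers, 64-dimensional embeddings, 4 heads) are
#' small enough to train on one CPU core in minutes; larger presets are
#' reachable through the same fields. `mixed_precision` is accepted for
#' interface compatibility but computation is always double precision.
#'
#' @param n_layers,embedding_dim,n_heads Transformer size;
#'   `embedding_dim` must be divisible by `n_heads`.
#' @param batch_size Minibatch size.
#' @param max_sequence_length Positions per sequence (visit cap + 4
#'   special positions); usually derived from the schema by
#'   [train_engine()] when `NULL`.
#' @param learning_rate Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param seed Integer seed; training is deterministic given the seed in
#'   single-threaded BLAS mode.
#' @param temperature Sampling temperature applied to logits at
#'   generation time.
#' @param mixed_precision Ignored (kept for config compatibility).
#' @return An `engine_config` list.
#' @export
engine_config <- function(n_layers = 2L, embedding_dim = 64L, n_heads = 4L,
                          batch_size = 64L, max_sequence_length = NULL,
                          learning_rate = 1e-2, epochs = 20L, patience = 5L,
                          seed = 1L, temperature = 1, mixed_precision = FALSE) {
  stopifnot(embedding_dim %% n_heads == 0)
  structure(list(n_layers = as.integer(n_layers),
                 embedding_dim = as.integer(embedding_dim),
                 n_heads = as.integer(n_heads),
                 batch_size = as.integer(batch_size),
                 max_sequence_length = max_sequence_length,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 temperature = temperature,
                 mixed_precision = isTRUE(mixed_precision)),
            class = "engine_config")
}

# Build padded dense sequence data from a tokenized cohort.
# Returns list(X: (N*S) x V, lens: N, S, V).
build_sequences <- function(tokenized, S) {
  V <- length(tokenized$vocab)
  prov <- tokenized$provenance
  i_start <- prov$index[prov$token == TOK_START]
  i_eov <- prov$index[prov$token == TOK_EOV]
  i_eor <- prov$index[prov$token == TOK_EOR]
  label_set <- prov$index[prov$role == "label"]
  recs <- tokenized$records
  N <- length(recs)
  lens <- integer(N)
  ii <- integer(0); jj <- integer(0)
  for (b in seq_len(N)) {
    r <- recs[[b]]
    k <- length(r$visits)
    len <- min(k + 4L, S)
    lens[b] <- len
    base <- (b - 1L) * S
    rows <- base + 1L; cols <- i_start
    labs <- r$static[r$static %in% label_set]
    stat <- r$static[!r$static %in% label_set]
    if (length(labs) > 0) {
      rows <- c(rows, rep(base + 2L, length(labs)))
      cols <- c(cols, labs)
    }
    if (length(stat) > 0) {
      rows <- c(rows, rep(base + 3L, length(stat)))
      cols <- c(cols, stat)
    }
    nvis <- min(k, S - 4L)
    for (v in seq_len(nvis)) {
      tok <- c(r$visits[[v]], i_eov)
      rows <- c(rows, rep(base + 3L + v, length(tok)))
      cols <- c(cols, tok)
    }
    rows <- c(rows, base + 3L + nvis + 1L); cols <- c(cols, i_eor)
    ii <- c(ii, rows); jj <- c(jj, cols)
  }
  X <- matrix(0, N * S, V)
  X[cbind(ii, jj)] <- 1
  list(X = X, lens = lens, S = S, V = V, N = N)
}

# Targets/valid mask for next-position prediction on a row slice.
seq_targets <- function(X, lens, B, S) {
  ipos <- rep(seq_len(S), B)
  sample_id <- rep(seq_len(B), each = S)
  valid_row <- ipos < lens[sample_id]
  Y <- matrix(0, nrow(X), ncol(X))
  w <- which(valid_row)
  Y[w, ] <- X[w + 1L, , drop = FALSE]
  list(Y = Y, valid_row = valid_row)
}

#' Train the visit-sequence engine on a tokenized cohort
#'
#' Minimises numerically stable binary cross-entropy (from logits) with
#' Adam; validation loss is computed each epoch and the parameters with the
#' best validation loss are returned (early stopping after
#' `config$patience` epochs without improvement). Deterministic for a given
#' `config$seed` under single-threaded BLAS.
#'
#' @param tokenized_train,tokenized_val `tokenized_cohort` objects sharing
#'   one vocabulary.
#' @param config An [engine_config()].
#' @return A `generator_model` holding the learned parameters, the
#'   configuration, the vocabulary and its provenance, and the training
#'   history.
#' @export
train_engine <- function(tokenized_train, tokenized_val, config = engine_config()) {
  if (length(tokenized_train$records) == 0) stop("empty training set")
  if (!identical(tokenized_train$vocab, tokenized_val$vocab))
    stop("train/validation vocabulary mismatch")
  S <- config$max_sequence_length %||%
    (tokenized_train$schema$max_visits + 4L)
  config$max_sequence_length <- S
  V <- length(tokenized_train$vocab)
  tr <- build_sequences(tokenized_train, S)
  va <- build_sequences(tokenized_val, S)
  va_tg <- seq_targets(va$X, va$lens, va$N, S)

  set.seed(config$seed)
  params <- nn_init_params(V, config$embedding_dim, config$n_layers,
                           config$n_heads, S)
  # initialise the output bias at the marginal token log-odds of the
  # training data: calibration starts at the empirical marginal and the
  # optimiser spends its steps on the conditional structure
  tr_tg <- seq_targets(tr$X, tr$lens, tr$N, S)
  marg <- colMeans(tr_tg$Y[tr_tg$valid_row, , drop = FALSE])
  marg <- pmin(pmax(marg, 1e-4), 1 - 1e-4)
  params$bout <- log(marg / (1 - marg))
  state <- nn_adam_init()
  N <- tr$N
  bs <- min(config$batch_size, N)
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- list()
  stale <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(N)
    tr_loss <- 0; nb <- 0
    for (start in seq(1, N, by = bs)) {
      idx <- ord[start:min(start + bs - 1, N)]
      B <- length(idx)
      rows <- as.vector(outer(seq_len(S), (idx - 1L) * S, "+"))
      Xb <- tr$X[rows, , drop = FALSE]
      tg <- seq_targets(Xb, tr$lens[idx], B, S)
      fwd <- nn_forward(params, Xb, B, S, want_cache = TRUE)
      lg <- nn_loss_and_grad(fwd$logits, tg$Y, tg$valid_row)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", epoch,
             " (learning rate too high?)")
      grads <- nn_backward(params, fwd, lg$dlogits, B, S)
      params <- nn_adam_step(params, grads, state, lr = config$learning_rate)
      tr_loss <- tr_loss + lg$loss; nb <- nb + 1
    }
    val_loss <- eval_loss(params, va, va_tg, S)
    history[[epoch]] <- c(epoch = epoch, train = tr_loss / nb, val = val_loss)
    if (val_loss < best$loss - 1e-7) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  structure(list(
    config = config,
    params = best$params,
    vocab = tokenized_train$vocab,
    provenance = tokenized_train$provenance,
    schema = tokenized_train$schema,
    vocab_fingerprint = vocab_fingerprint(tokenized_train$vocab),
    history = dplyr::bind_rows(lapply(history, as.list)),
    best_val_loss = best$loss
  ), class = "generator_model")
}

# chunked full-data loss (keeps memory bounded)
eval_loss <- function(params, seqs, tg, S, chunk = 256L) {
  N <- seqs$N
  tot <- 0; n <- 0
  for (start in seq(1, N, by = chunk)) {
    idx <- start:min(start + chunk - 1, N)
    rows <- as.vector(outer(seq_len(S), (idx - 1L) * S, "+"))
    vr <- tg$valid_row[rows]
    fwd <- nn_forward(params, seqs$X[rows, , drop = FALSE], length(idx), S)
    tot <- tot + sum(nn_bce(fwd$logits[vr, , drop = FALSE],
                            tg$Y[rows, , drop = FALSE][vr, , drop = FALSE]))
    n <- n + sum(vr)
  }
  tot / (n * seqs$V)
}

vocab_fingerprint <- function(vocab) {
  x <- paste(vocab, collapse = "|")
  sprintf("v%d-%08x", length(vocab),
          sum(utf8ToInt(x) * (seq_len(nchar(x)) %% 97 + 1)) %% .Machine$integer.max)
}

#' @export
print.generator_model <- function(x, ...) {
  cat("<generator_model> ", x$config$n_layers, " layers, dim ",
      x$config$embedding_dim, ", vocab ", length(x$vocab),
      ", best val loss ", format(x$best_val_loss, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Mean per-position log-loss of a model on held-out data
#'
#' The mean over predicted positions of the summed binary cross-entropy
#' across the vocabulary (natural log), a likelihood-style model-selection
#' proxy: a model emitting 0.5 everywhere scores `V * log(2)`.
#'
#' @param model A `generator_model`.
#' @param tokenized_test A `tokenized_cohort` with the same vocabulary.
#' @return Mean per-position log-loss (scalar).
#' @export
perplexity_proxy <- function(model, tokenized_test) {
  if (length(tokenized_test$records) == 0) stop("empty test set")
  if (!identical(model$vocab, tokenized_test$vocab))
    stop("vocabulary mismatch between model and test cohort")
  S <- model$config$max_sequence_length
  te <- build_sequences(tokenized_test, S)
  tg <- seq_targets(te$X, te$lens, te$N, S)
  tot <- 0; n <- 0
  for (start in seq(1, te$N, by = 256L)) {
    idx <- start:min(start + 255L, te$N)
    rows <- as.vector(outer(seq_len(S), (idx - 1L) * S, "+"))
    vr <- tg$valid_row[rows]
    fwd <- nn_forward(model$params, te$X[rows, , drop = FALSE],
                      length(idx), S)
    tot <- tot + sum(nn_bce(fwd$logits[vr, , drop = FALSE],
                            tg$Y[rows, , drop = FALSE][vr, , drop = FALSE]))
    n <- n + sum(vr)
  }
  tot / n
}
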