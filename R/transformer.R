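# Internal neural-network machinery for the visit-sequence engine.
#
# A small pre-LayerNorm causal transformer over multi-hot visit vectors:
# each sequence position holds a binary vector over the token vocabulary and
# the model predicts the next position's multi-hot vector through a sigmoid
# output layer. The forward pass returns raw logits; the loss is a
# numerically stable binary cross-entropy computed from logits. All shapes
# are kept as flat (batch*position) x feature matrices so every step is a
# BLAS-backed matrix operation; attention uses an O(seq_len) loop of
# vectorised row operations rather than per-sample loops.
#
# Row ordering convention: sample-major. Row (b-1)*S + t holds position t of
# sample b. All functions below assume this layout.

nn_init_params <- function(vocab_size, embed_dim, n_layers, n_heads,
                           max_seq_len, init_sd = 0.02) {
  stopifnot(embed_dim %% n_heads == 0)
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = init_sd), nr, nc)
  blocks <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    blocks[[l]] <- list(
      ln1_g = rep(1, embed_dim), ln1_b = rep(0, embed_dim),
      Wq = rn(embed_dim, embed_dim), bq = rep(0, embed_dim),
      Wk = rn(embed_dim, embed_dim), bk = rep(0, embed_dim),
      Wv = rn(embed_dim, embed_dim), bv = rep(0, embed_dim),
      Wo = rn(embed_dim, embed_dim), bo = rep(0, embed_dim),
      ln2_g = rep(1, embed_dim), ln2_b = rep(0, embed_dim),
      W1 = rn(embed_dim, 4L * embed_dim), b1 = rep(0, 4L * embed_dim),
      W2 = rn(4L * embed_dim, embed_dim), b2 = rep(0, embed_dim)
    )
  }
  list(
    Win = rn(vocab_size, embed_dim),
    Pos = rn(max_seq_len, embed_dim),
    blocks = blocks,
    lnf_g = rep(1, embed_dim), lnf_b = rep(0, embed_dim),
    Wout = rn(embed_dim, vocab_size), bout = rep(0, vocab_size),
    dims = list(vocab_size = vocab_size, embed_dim = embed_dim,
                n_layers = n_layers, n_heads = n_heads,
                max_seq_len = max_seq_len)
  )
}

# Broadcast helpers: g/b are length-D, x is M x D.
.scale_cols <- function(x, g) x * rep(g, each = nrow(x))
.add_cols <- function(x, b) x + rep(b, each = nrow(x))

nn_ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd_inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * sd_inv
  list(y = .add_cols(.scale_cols(xhat, g), b), xhat = xhat, sd_inv = sd_inv)
}

nn_ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- .scale_cols(dy, g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$sd_inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# Multi-head causal self-attention forward over a flat M x D matrix.
# B samples of S positions each; ipos = rep(1:S, B) gives each row's position.
nn_attn_fwd <- function(a, blk, B, S, n_heads) {
  D <- ncol(a)
  dh <- D %/% n_heads
  M <- nrow(a)
  Q <- .add_cols(a %*% blk$Wq, blk$bq)
  K <- .add_cols(a %*% blk$Wk, blk$bk)
  V <- .add_cols(a %*% blk$Wv, blk$bv)
  ipos <- rep(seq_len(S), B)
  O <- matrix(0, M, D)
  P_list <- vector("list", n_heads)
  scale <- 1 / sqrt(dh)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- Q[, cols, drop = FALSE]
    Kh <- K[, cols, drop = FALSE]
    Vh <- V[, cols, drop = FALSE]
    Sc <- matrix(-1e30, M, S)
    for (j in seq_len(S)) {
      idx_j <- (seq_len(B) - 1L) * S + j
      Kexp <- Kh[rep(idx_j, each = S), , drop = FALSE]
      sc_j <- rowSums(Qh * Kexp) * scale
      sc_j[ipos < j] <- -1e30
      Sc[, j] <- sc_j
    }
    mx <- Sc[, 1]
    for (j in seq_len(S)[-1]) mx <- pmax(mx, Sc[, j])
    P <- exp(Sc - mx)
    P <- P / rowSums(P)
    Oh <- matrix(0, M, dh)
    for (j in seq_len(S)) {
      idx_j <- (seq_len(B) - 1L) * S + j
      Vexp <- Vh[rep(idx_j, each = S), , drop = FALSE]
      Oh <- Oh + P[, j] * Vexp
    }
    O[, cols] <- Oh
    P_list[[h]] <- P
  }
  out <- .add_cols(O %*% blk$Wo, blk$bo)
  list(out = out, Q = Q, K = K, V = V, O = O, P_list = P_list)
}

nn_attn_bwd <- function(dout, cache, a, blk, B, S, n_heads) {
  D <- ncol(a)
  dh <- D %/% n_heads
  M <- nrow(a)
  sample_id <- rep(seq_len(B), each = S)
  scale <- 1 / sqrt(dh)
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- dout %*% t(blk$Wo)
  dQ <- matrix(0, M, D); dK <- matrix(0, M, D); dV <- matrix(0, M, D)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- cache$Q[, cols, drop = FALSE]
    Kh <- cache$K[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    P <- cache$P_list[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dP <- matrix(0, M, S)
    dVh <- matrix(0, M, dh)
    for (j in seq_len(S)) {
      idx_j <- (seq_len(B) - 1L) * S + j
      Vexp <- Vh[rep(idx_j, each = S), , drop = FALSE]
      dP[, j] <- rowSums(dOh * Vexp)
      contrib <- rowsum(P[, j] * dOh, sample_id, reorder = FALSE)
      dVh[idx_j, ] <- dVh[idx_j, ] + contrib
    }
    dSc <- P * (dP - rowSums(dP * P))
    dQh <- matrix(0, M, dh)
    dKh <- matrix(0, M, dh)
    for (j in seq_len(S)) {
      idx_j <- (seq_len(B) - 1L) * S + j
      Kexp <- Kh[rep(idx_j, each = S), , drop = FALSE]
      dQh <- dQh + (dSc[, j] * scale) * Kexp
      dKh[idx_j, ] <- dKh[idx_j, ] +
        rowsum((dSc[, j] * scale) * Qh, sample_id, reorder = FALSE)
    }
    dQ[, cols] <- dQh; dK[, cols] <- dKh; dV[, cols] <- dVh
  }
  da <- dQ %*% t(blk$Wq) + dK %*% t(blk$Wk) + dV %*% t(blk$Wv)
  list(da = da,
       dWq = crossprod(a, dQ), dbq = colSums(dQ),
       dWk = crossprod(a, dK), dbk = colSums(dK),
       dWv = crossprod(a, dV), dbv = colSums(dV),
       dWo = dWo, dbo = dbo)
}

# Full forward pass. X: M x V multi-hot (M = B*S, sample-major).
# Returns logits and, when want_cache, intermediates for the backward pass.
# logits_rows restricts the output projection to selected rows (used in
# generation, where only the last position's prediction is needed).
nn_forward <- function(params, X, B, S, want_cache = FALSE,
                       logits_rows = NULL) {
  d <- params$dims
  ipos <- rep(seq_len(S), B)
  h <- X %*% params$Win + params$Pos[ipos, , drop = FALSE]
  caches <- if (want_cache) vector("list", d$n_layers) else NULL
  for (l in seq_len(d$n_layers)) {
    blk <- params$blocks[[l]]
    ln1 <- nn_ln_fwd(h, blk$ln1_g, blk$ln1_b)
    at <- nn_attn_fwd(ln1$y, blk, B, S, d$n_heads)
    h1 <- h + at$out
    ln2 <- nn_ln_fwd(h1, blk$ln2_g, blk$ln2_b)
    Z1 <- .add_cols(ln2$y %*% blk$W1, blk$b1)
    R <- Z1 * (Z1 > 0)
    mlp <- .add_cols(R %*% blk$W2, blk$b2)
    h2 <- h1 + mlp
    if (want_cache) {
      caches[[l]] <- list(ln1 = ln1, at = at, h1 = h1, ln2 = ln2,
                          relu_mask = (Z1 > 0), R = R)
    }
    h <- h2
  }
  if (!is.null(logits_rows)) h <- h[logits_rows, , drop = FALSE]
  lnf <- nn_ln_fwd(h, params$lnf_g, params$lnf_b)
  logits <- .add_cols(lnf$y %*% params$Wout, params$bout)
  list(logits = logits, lnf = lnf, caches = caches, X = X, ipos = ipos)
}

# Stable elementwise BCE-with-logits; targets in {0,1}.
nn_bce <- function(logits, targets) {
  pmax(logits, 0) - logits * targets + log1p(exp(-abs(logits)))
}

# Loss over valid rows only. valid_row: logical length M marking rows whose
# prediction (of the NEXT position) enters the loss; targets Y aligned to
# those rows (Y[r, ] = tokens of position r+1 within the same sample).
nn_loss_and_grad <- function(logits, Y, valid_row) {
  nvalid <- sum(valid_row)
  V <- ncol(logits)
  L <- logits[valid_row, , drop = FALSE]
  Yv <- Y[valid_row, , drop = FALSE]
  loss <- sum(nn_bce(L, Yv)) / (nvalid * V)
  dG <- matrix(0, nrow(logits), V)
  dG[valid_row, ] <- (1 / (1 + exp(-L)) - Yv) / (nvalid * V)
  list(loss = loss, dlogits = dG)
}

nn_backward <- function(params, fwd, dlogits, B, S) {
  d <- params$dims
  grads <- list()
  grads$Wout <- crossprod(fwd$lnf$y, dlogits)
  grads$bout <- colSums(dlogits)
  dAf <- dlogits %*% t(params$Wout)
  lb <- nn_ln_bwd(dAf, fwd$lnf, params$lnf_g)
  grads$lnf_g <- lb$dg; grads$lnf_b <- lb$db
  dh <- lb$dx
  grads$blocks <- vector("list", d$n_layers)
  for (l in rev(seq_len(d$n_layers))) {
    blk <- params$blocks[[l]]
    cc <- fwd$caches[[l]]
    # MLP branch
    dmlp <- dh
    gW2 <- crossprod(cc$R, dmlp)
    gb2 <- colSums(dmlp)
    dR <- dmlp %*% t(blk$W2)
    dZ1 <- dR * cc$relu_mask
    gW1 <- crossprod(cc$ln2$y, dZ1)
    gb1 <- colSums(dZ1)
    dln2y <- dZ1 %*% t(blk$W1)
    lb2 <- nn_ln_bwd(dln2y, cc$ln2, blk$ln2_g)
    dh1 <- dh + lb2$dx
    # attention branch
    ab <- nn_attn_bwd(dh1, cc$at, cc$ln1$y, blk, B, S, d$n_heads)
    lb1 <- nn_ln_bwd(ab$da, cc$ln1, blk$ln1_g)
    dh <- dh1 + lb1$dx
    grads$blocks[[l]] <- list(
      ln1_g = lb1$dg, ln1_b = lb1$db,
      Wq = ab$dWq, bq = ab$dbq, Wk = ab$dWk, bk = ab$dbk,
      Wv = ab$dWv, bv = ab$dbv, Wo = ab$dWo, bo = ab$dbo,
      ln2_g = lb2$dg, ln2_b = lb2$db,
      W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2
    )
  }
  grads$Win <- crossprod(fwd$X, dh)
  grads$Pos <- rowsum(dh, fwd$ipos, reorder = TRUE)
  grads
}

# ---- flat parameter <-> list utilities (used by Adam and gradient checks) ----

nn_param_names <- function(params) {
  top <- c("Win", "Pos", "lnf_g", "lnf_b", "Wout", "bout")
  blk <- c("ln1_g", "ln1_b", "Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
           "ln2_g", "ln2_b", "W1", "b1", "W2", "b2")
  list(top = top, blk = blk)
}

nn_apply_update <- function(params, grads, fn) {
  nm <- nn_param_names(params)
  for (p in nm$top) params[[p]] <- fn(params[[p]], grads[[p]], p)
  for (l in seq_along(params$blocks)) {
    for (p in nm$blk) {
      key <- paste0("b", l, ".", p)
      params$blocks[[l]][[p]] <-
        fn(params$blocks[[l]][[p]], grads$blocks[[l]][[p]], key)
    }
  }
  params
}

nn_adam_init <- function() new.env(parent = emptyenv())

nn_adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  state$t <- (state$t %||% 0) + 1
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  nn_apply_update(params, grads, function(w, g, key) {
    if (is.null(g)) return(w)
    m <- state[[paste0("m.", key)]]
    v <- state[[paste0("v.", key)]]
    if (is.null(m)) { m <- w * 0; v <- w * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state[[paste0("m.", key)]] <- m
    state[[paste0("v.", key)]] <- v
    w - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
}

# Convenience: loss of a batch without gradient (used for validation).
nn_batch_loss <- function(params, X, Y, valid_row, B, S) {
  fwd <- nn_forward(params, X, B, S, want_cache = FALSE)
  nvalid <- sum(valid_row)
  V <- ncol(fwd$logits)
  sum(nn_bce(fwd$logits[valid_row, , drop = FALSE],
             Y[valid_row, , drop = FALSE])) / (nvalid * V)
}
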