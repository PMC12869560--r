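test_that("classification metrics match closed forms", {
  scores <- c(0.9, 0.8, 0.4, 0.3, 0.6, 0.2)
  labels <- c(1, 1, 1, 0, 0, 0)
  m <- classification_metrics(scores, labels)
  expect_equal(unname(m["precision"]), 2 / 3)
  expect_equal(unname(m["recall"]), 2 / 3)
  expect_equal(unname(m["f1"]), 2 / 3)
  # rank-statistic AUC against pROC as an independent implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(unname(m["roc_auc"]),
                 as.numeric(suppressMessages(pROC::auc(labels, scores))))
  }
  # perfect separation
  mp <- classification_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(unname(mp[c("precision", "recall", "f1", "pr_auc",
                           "roc_auc")]), rep(1, 5))
})

test_that("identical training data gives identical metric rows", {
  fx <- tstr_fixture()
  res2 <- tstr_evaluate(fx$parts$train, fx$parts$train, fx$parts$test,
                        fx$task, seed = 3)
  m <- res2$metrics
  expect_equal(m[m$training_data == "real", -1],
               m[m$training_data == "synth", -1])
  expect_error(tstr_evaluate(fx$parts$train, fx$parts$train,
                             fx$parts$train, fx$task, seed = 3),
               "shares patients")
})

test_that("a label predictable from features is learned near-perfectly", {
  fx <- tstr_fixture()
  # the diabetes label is (almost) determined by the E11 family flag
  m <- fx$res$metrics
  expect_gt(m$roc_auc[m$training_data == "real"], 0.97)
  expect_gt(m$f1[m$training_data == "real"], 0.9)
})

test_that("labels independent of features give chance-level AUC", {
  set.seed(14)
  n <- 4000
  X <- matrix(stats::rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- stats::rbinom(n, 1, 0.3)
  fit <- fit_gbm(X[1:3000, ], y[1:3000], seed = 2)
  sc <- stats::predict(fit, X[3001:n, ])
  expect_lt(abs(roc_auc(sc, y[3001:n]) - 0.5), 0.05)
  expect_error(fit_gbm(X, rep(1, n), seed = 2), "single-class")
})

test_that("attribution ranks agree with exhaustive Shapley enumeration", {
  set.seed(15)
  n <- 600
  X <- matrix(stats::rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  # additive signal with clearly ordered effect sizes
  eta <- 2.0 * X[, 1] + 1.0 * X[, 2] + 0.4 * X[, 3] + 0 * X[, 4]
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  fit <- fit_gbm(X, y, seed = 4, nrounds = 80)
  imp <- shap_importance(fit, X)
  # brute-force Shapley values with the empirical marginal background
  bg <- X[1:100, ]
  fhat <- function(M) stats::predict(fit, M, outputmargin = TRUE)
  coalitions <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  eval_rows <- X[101:200, ]
  phi <- matrix(0, nrow(eval_rows), 4)
  vfun <- function(row, S) {
    M <- bg
    M[, S] <- matrix(rep(row[S], each = nrow(bg)), nrow(bg))
    mean(fhat(M))
  }
  for (r in seq_len(nrow(eval_rows))) {
    row <- eval_rows[r, ]
    vcache <- apply(coalitions, 1, function(S) vfun(row, as.logical(S)))
    for (j in 1:4) {
      tot <- 0
      for (ci in seq_len(nrow(coalitions))) {
        S <- as.logical(coalitions[ci, ])
        if (S[j]) next
        Sj <- S; Sj[j] <- TRUE
        cj <- which(apply(coalitions, 1, function(z)
          identical(as.logical(z), Sj)))
        w <- factorial(sum(S)) * factorial(4 - sum(S) - 1) / factorial(4)
        tot <- tot + w * (vcache[cj] - vcache[ci])
      }
      phi[r, j] <- tot
    }
  }
  brute_imp <- colMeans(abs(phi))
  expect_identical(order(-imp), order(-brute_imp))
  # self-comparison is a perfect rank agreement
  agree <- attribution_rank_agreement(fit, fit, X, k = 4)
  expect_equal(agree$spearman_rho, 1)
  expect_equal(agree$top_k_overlap, 4)
})

test_that("equal opportunity gaps follow their arithmetic definition", {
  # two groups with TPR 0.9 and 0.6
  labels <- rep(1, 200)
  groups <- rep(c("a", "b"), each = 100)
  scores <- c(rep(0.9, 90), rep(0.1, 10), rep(0.9, 60), rep(0.1, 40))
  eo <- equal_opportunity(scores, labels, groups)
  expect_equal(eo$gap, 0.3)
  expect_equal(unname(eo$tpr), c(0.9, 0.6))
  # identical TPRs give a zero gap
  eo0 <- equal_opportunity(rep(c(0.9, 0.1), 100), rep(1, 200), groups)
  expect_equal(eo0$gap, 0)
  # invariance to patient order and group relabeling
  set.seed(16)
  n <- 10000
  g <- sample(c("x", "y", "z"), n, replace = TRUE)
  lab <- stats::rbinom(n, 1, 0.4)
  sc <- stats::runif(n)
  e1 <- equal_opportunity(sc, lab, g)
  perm <- sample(n)
  e2 <- equal_opportunity(sc[perm], lab[perm], g[perm])
  expect_equal(e1$gap, e2$gap)
  relab <- c(x = "q", y = "r", z = "s")[g]
  e3 <- equal_opportunity(sc, lab, relab)
  expect_equal(e1$gap, e3$gap)
  # group-independent scores give a near-zero gap
  expect_lt(e1$gap, 0.05)
  # a group without positives is excluded with a warning
  lab2 <- lab; lab2[g == "z"] <- 0
  expect_warning(e4 <- equal_opportunity(sc, lab2, g), "no positive")
  expect_equal(length(e4$tpr), 2)
})
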