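# Train-on-synthetic / test-on-real machine-learning utility, feature
# attribution agreement and equal-opportunity fairness.

#' Define a prediction task over a cohort
#'
#' A task names a label extractor mapping a cohort to one feature row plus
#' binary outcome per patient; extractors must only use information
#' available before the prediction time.
#'
#' @param name Task name.
#' @param extract `function(cohort)` returning a tibble with
#'   `patient_id`, `label` (0/1) and numeric feature columns.
#' @param group_vars Character columns kept for subgroup (fairness)
#'   analysis but excluded from the feature matrix.
#' @return A `task_spec`.
#' @export
task_spec <- function(name, extract, group_vars = character(0)) {
  structure(list(name = name, extract = extract, group_vars = group_vars),
            class = "task_spec")
}

#' Built-in task: predict a static condition label
#'
#' Label is the patient's binary condition flag; features are age, gender,
#' visit count, mean inter-visit gap and presence flags for the other code
#' families (the label's own code family is excluded to avoid leakage).
#'
#' @param label_field Name of the static label column.
#' @param exclude_prefix Code prefix to drop from the features (defaults
#'   to none).
#' @return A [task_spec()].
#' @export
task_condition_label <- function(label_field, exclude_prefix = NULL) {
  task_spec(paste0("label_", label_field), function(cohort) {
    pat <- cohort$patients
    rows <- cohort_analysis_rows(cohort)
    agg <- dplyr::summarise(dplyr::group_by(rows, .data$patient_id),
                            n_visits = dplyr::n(),
                            mean_gap = mean(.data$gap_days, na.rm = TRUE),
                            .groups = "drop")
    agg$mean_gap[!is.finite(agg$mean_gap)] <- 0
    out <- tibble::tibble(
      patient_id = pat$patient_id,
      label = as.integer(pat[[label_field]]),
      age = pat$age,
      female = as.integer(pat$gender == "F"))
    out <- dplyr::left_join(out, agg, by = "patient_id")
    out$n_visits[is.na(out$n_visits)] <- 0
    out$mean_gap[is.na(out$mean_gap)] <- 0
    prefixes <- sort(unique(substr(cohort$diagnoses$code, 1, 3)))
    if (!is.null(exclude_prefix))
      prefixes <- setdiff(prefixes, exclude_prefix)
    for (p in prefixes) {
      carriers <- unique(cohort$diagnoses$patient_id[
        startsWith(cohort$diagnoses$code, p)])
      out[[paste0("fam_", p)]] <- as.integer(out$patient_id %in% carriers)
    }
    out
  }, group_vars = c("female"))
}

#' Built-in task: 30-day revisit after the first visit
#'
#' Label: the patient's second visit starts within `days` of the first
#' visit's start; features come from the first visit only.
#' @param days Revisit window in days.
#' @return A [task_spec()].
#' @export
task_revisit <- function(days = 30) {
  task_spec(paste0("revisit_", days, "d"), function(cohort) {
    vis <- dplyr::arrange(cohort$visits, .data$patient_id, .data$start_time)
    vis$.seq <- stats::ave(seq_len(nrow(vis)), vis$patient_id,
                           FUN = seq_along)
    f <- vis[vis$.seq == 1, ]
    s <- vis[vis$.seq == 2, c("patient_id", "start_time")]
    names(s)[2] <- "second_start"
    f <- dplyr::left_join(f, s, by = "patient_id")
    lab <- as.integer(!is.na(f$second_start) &
                        as.numeric(difftime(f$second_start, f$start_time,
                                            units = "days")) <= days)
    pat <- cohort$patients
    out <- tibble::tibble(patient_id = f$patient_id, label = lab)
    out$age <- pat$age[match(out$patient_id, pat$patient_id)]
    out$female <- as.integer(pat$gender[match(out$patient_id,
                                              pat$patient_id)] == "F")
    if ("los_total" %in% names(f)) {
      out$los_total <- f$los_total
      out$los_total[is.na(out$los_total)] <- 0
    }
    if ("event_type" %in% names(f)) {
      lv <- sort(unique(f$event_type))
      for (l in lv[-1])
        out[[paste0("etype_", l)]] <- as.integer(f$event_type == l)
    }
    out
  }, group_vars = c("female"))
}

#' Built-in task: outcome code at a later visit given first-visit features
#'
#' Label: any code of `outcome_set` appears at a visit after the first;
#' features are first-visit code presence flags plus demographics.
#' @param outcome_set Character codes defining the outcome.
#' @return A [task_spec()].
#' @export
task_next_code <- function(outcome_set) {
  task_spec("next_code", function(cohort) {
    vis <- dplyr::arrange(cohort$visits, .data$patient_id, .data$start_time)
    vis$.seq <- stats::ave(seq_len(nrow(vis)), vis$patient_id,
                           FUN = seq_along)
    dx <- cohort$diagnoses
    dx$.seq <- vis$.seq[match(paste(dx$patient_id, dx$visit_id),
                              paste(vis$patient_id, vis$visit_id))]
    later <- unique(dx$patient_id[dx$code %in% outcome_set & dx$.seq > 1])
    pat <- cohort$patients
    out <- tibble::tibble(patient_id = pat$patient_id,
                          label = as.integer(pat$patient_id %in% later),
                          age = pat$age,
                          female = as.integer(pat$gender == "F"))
    first_dx <- dx[dx$.seq == 1 & !is.na(dx$.seq), ]
    for (p in sort(unique(substr(first_dx$code, 1, 3)))) {
      carriers <- unique(first_dx$patient_id[startsWith(first_dx$code, p)])
      out[[paste0("first_", p)]] <- as.integer(out$patient_id %in% carriers)
    }
    out
  }, group_vars = c("female"))
}

task_matrix <- function(task_df, feature_names = NULL) {
  feats <- setdiff(names(task_df), c("patient_id", "label"))
  if (!is.null(feature_names)) {
    for (f in setdiff(feature_names, feats)) task_df[[f]] <- 0
    feats <- feature_names
  }
  X <- as.matrix(task_df[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = task_df$label, features = feats,
       patient_id = task_df$patient_id)
}

fit_gbm <- function(X, y, seed, nrounds = 200, max_depth = 4, eta = 0.1) {
  if (length(unique(y)) < 2) stop("single-class training labels")
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   max_depth = max_depth, eta = eta,
                                   nthread = 1, seed = seed),
                     data = dtrain, nrounds = nrounds, verbose = 0)
}

#' Binary classification metrics at threshold 0.5
#'
#' Precision, recall, F1 (threshold 0.5), PR AUC (average precision over
#' recall steps) and ROC AUC (rank statistic).
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels.
#' @return Named numeric vector.
#' @export
classification_metrics <- function(scores, labels) {
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1,
    pr_auc = pr_auc(scores, labels), roc_auc = roc_auc(scores, labels))
}

roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# average precision (step-wise integral of the PR curve)
pr_auc <- function(scores, labels) {
  if (sum(labels == 1) == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

#' Train-on-synthetic / test-on-real evaluation
#'
#' One gradient-boosted tree classifier (fixed hyperparameters: depth 4,
#' 200 trees, learning rate 0.1, single thread, fixed seed) per training
#' condition — real, synthetic, and real + synthetic — each evaluated on
#' the same held-out real test set with precision, recall, F1 (threshold
#' 0.5), PR AUC and ROC AUC.
#'
#' @param train_real,train_synth,test_real [ehr_cohort()] objects;
#'   `test_real` must be patient-disjoint from `train_real`.
#' @param task A [task_spec()].
#' @param seed Integer seed.
#' @return A `tstr_result`: `metrics` tibble (one row per training
#'   condition), fitted `models`, the `features` used and the test
#'   extraction.
#' @export
tstr_evaluate <- function(train_real, train_synth, test_real, task, seed = 1L) {
  tr <- task$extract(train_real)
  ts <- task$extract(train_synth)
  te <- task$extract(test_real)
  if (any(te$patient_id %in% tr$patient_id))
    stop("test_real shares patients with train_real")
  mr <- task_matrix(tr)
  feats <- mr$features
  ms <- task_matrix(ts, feats)
  mte <- task_matrix(te, feats)
  conds <- list(real = mr,
                synth = ms,
                `real+synth` = list(X = rbind(mr$X, ms$X),
                                    y = c(mr$y, ms$y), features = feats))
  models <- list()
  rows <- list()
  for (cn in names(conds)) {
    cc <- conds[[cn]]
    fit <- fit_gbm(cc$X, cc$y, seed = seed)
    models[[cn]] <- fit
    sc <- stats::predict(fit, mte$X)
    rows[[cn]] <- tibble::as_tibble_row(
      c(classification_metrics(sc, mte$y)))
  }
  metrics <- dplyr::bind_rows(rows, .id = "training_data")
  structure(list(metrics = metrics, models = models, features = feats,
                 test = mte, task = task$name, seed = seed),
            class = "tstr_result")
}

#' @export
print.tstr_result <- function(x, ...) {
  cat("<tstr_result> task '", x$task, "'\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Mean absolute Shapley attributions of a fitted tree model
#'
#' Exact tree-path attributions (TreeSHAP) on the test features.
#' @param model An xgboost model from [tstr_evaluate()].
#' @param X Feature matrix.
#' @return Named vector of mean absolute attributions.
#' @export
shap_importance <- function(model, X) {
  contrib <- stats::predict(model, X, predcontrib = TRUE)
  contrib <- contrib[, setdiff(colnames(contrib), c("BIAS", "(Intercept)")),
                     drop = FALSE]
  colMeans(abs(contrib))
}

#' Attribution-rank agreement between two models
#'
#' Features are ranked by mean absolute Shapley-style attribution on the
#' same real test set; reports the size of the top-`k` overlap and the
#' Spearman rank correlation over all features.
#'
#' @param model_real,model_synth Models over the same feature list.
#' @param test_X Real test feature matrix.
#' @param k Top-rank overlap size.
#' @return List `top_k_overlap`, `spearman_rho`, `importance` (tibble).
#' @export
attribution_rank_agreement <- function(model_real, model_synth, test_X,
                                       k = 10) {
  ir <- shap_importance(model_real, test_X)
  is_ <- shap_importance(model_synth, test_X)
  if (!identical(names(ir), names(is_)))
    stop("models were trained on different feature lists")
  k <- min(k, length(ir))
  top_r <- names(sort(ir, decreasing = TRUE))[seq_len(k)]
  top_s <- names(sort(is_, decreasing = TRUE))[seq_len(k)]
  rho <- stats::cor(ir, is_, method = "spearman")
  list(top_k_overlap = length(intersect(top_r, top_s)),
       spearman_rho = rho,
       importance = tibble::tibble(feature = names(ir), real = unname(ir),
                                   synth = unname(is_)))
}

#' Equal-opportunity gap of a classifier across subgroups
#'
#' True-positive rate per subgroup at threshold 0.5; the gap is the
#' maximum minus the minimum TPR over groups with at least one positive
#' case (groups without positives are excluded with a warning).
#'
#' @param scores Predicted probabilities on the test set.
#' @param labels 0/1 test labels.
#' @param groups Subgroup membership vector.
#' @return List `gap`, `tpr` (named per-group rates).
#' @export
equal_opportunity <- function(scores, labels, groups) {
  groups <- as.character(groups)
  tprs <- c()
  for (g in sort(unique(groups))) {
    sel <- groups == g & labels == 1
    if (!any(sel)) {
      warning("group '", g, "' has no positive cases; excluded")
      next
    }
    tprs[g] <- mean(scores[sel] >= 0.5)
  }
  if (length(tprs) < 2) stop("need at least two groups with positives")
  list(gap = max(tprs) - min(tprs), tpr = tprs)
}
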