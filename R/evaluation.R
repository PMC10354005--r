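# Scoring one chromosome: generation-seeded stratified k-fold CV,
# boosted-tree training with validation-AUC early stopping, and the
# ten-objective vector.

#' Build a generation-seeded stratified CV plan
#'
#' Folds partition the samples; per-fold class counts differ by at most
#' one from perfect proportionality. The shuffle is seeded with
#' `base_seed + generation`, so every solution of a generation sees the
#' same plan while consecutive generations see different splits.
#'
#' @param y Binary 0/1 vector.
#' @param k Number of folds (default 10).
#' @param base_seed Run-level seed.
#' @param generation Generation counter.
#' @return An `eb_cv_plan`: list of `k` disjoint validation index sets.
#' @export
make_cv_plan <- function(y, k = 10L, base_seed = 1L, generation = 0L) {
  n <- length(y)
  counts <- table(y)
  if (min(counts) < k)
    stopf("smallest class has %d members; use k <= %d", min(counts),
          min(counts))
  folds <- with_seed(base_seed + generation, {
    assign_fold <- integer(n)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      assign_fold[idx] <- rep_len(sample.int(k), length(idx))
    }
    lapply(seq_len(k), function(f) which(assign_fold == f))
  })
  structure(list(k = as.integer(k), folds = folds,
                 base_seed = base_seed, generation = generation),
            class = "eb_cv_plan")
}

#' Rank-based AUC with midrank ties
#'
#' @param y_true Binary 0/1 vector.
#' @param y_prob Positive-class scores.
#' @return AUC in \[0, 1\]; 0 when a class is absent.
#' @export
auc_score <- function(y_true, y_prob) {
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) return(0)
  r <- rank(y_prob)
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Weighted geometric mean of sensitivity and specificity
#'
#' `sensitivity^w * specificity^(1-w)`. The default weight used during
#' evaluation is the majority-class proportion, which up-weights
#' minority-class recall.
#'
#' @param sensitivity,specificity Values in \[0, 1\].
#' @param w Weight in \[0, 1\] on sensitivity.
#' @return The weighted geometric mean.
#' @export
wgm <- function(sensitivity, specificity, w = 0.5) {
  stopifnot(w >= 0, w <= 1)
  sensitivity^w * specificity^(1 - w)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Confusion-matrix and ranking metrics
#'
#' Standard confusion-matrix definitions with the convention that any
#' ratio with a zero denominator scores 0 (the worst value), pushing
#' selection away from degenerate confusion matrices.
#'
#' @param y_true Binary 0/1 vector.
#' @param y_pred Predicted 0/1 labels.
#' @param y_prob Positive-class probabilities (for AUC).
#' @param wgm_weight Sensitivity exponent for [wgm()].
#' @return Named list: accuracy, precision, recall, specificity,
#'   balanced_accuracy, f1, f2, auc, wgm.
#' @export
classification_metrics <- function(y_true, y_pred, y_prob = NULL,
                                   wgm_weight = 0.5) {
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_true == 1L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  f2 <- safe_div(5 * precision * recall, 4 * precision + recall)
  list(
    accuracy = safe_div(tp + tn, tp + tn + fp + fn),
    precision = precision, recall = recall, specificity = specificity,
    balanced_accuracy = (recall + specificity) / 2,
    f1 = f1, f2 = f2,
    auc = if (is.null(y_prob)) 0 else auc_score(y_true, y_prob),
    wgm = wgm(recall, specificity, wgm_weight)
  )
}

#' Feature-complexity objective
#'
#' `1 - n_active / p`: models using fewer features score higher.
#'
#' @param n_active Number of active features.
#' @param p Total number of features.
#' @return Value in \[0, 1\].
#' @export
feature_complexity <- function(n_active, p) {
  stopifnot(n_active >= 0, n_active <= p)
  1 - n_active / p
}

#' Split-complexity objective
#'
#' `max(0, 1 - mean_total_splits / s_max)`: boosted ensembles with fewer
#' internal split nodes score higher.
#'
#' @param mean_total_splits Mean (over folds) of the total internal
#'   split count of the retained trees.
#' @param s_max Split budget at which the score reaches 0 (default 256).
#' @return Value in \[0, 1\].
#' @export
split_complexity <- function(mean_total_splits, s_max = 256) {
  stopifnot(mean_total_splits >= 0)
  max(0, 1 - mean_total_splits / s_max)
}

#' Overall and weighted-overall scalar scores
#'
#' @param objectives Named numeric vector of the 10 objectives (see
#'   [objective_names()]).
#' @param weights Non-negative weights of length 10 with positive sum;
#'   `NULL` means equal weights.
#' @return List with `overall` (unweighted mean) and `weighted_overall`.
#' @export
overall_scores <- function(objectives, weights = NULL) {
  stopifnot(length(objectives) == 10L)
  weights <- weights %||% rep(1, 10L)
  if (length(weights) != 10L || any(weights < 0) || sum(weights) <= 0)
    stopf("weights must be 10 non-negative values with positive sum")
  list(overall = mean(objectives),
       weighted_overall = sum(weights * objectives) / sum(weights))
}

# Count internal split nodes over the first `n_trees` trees of a booster.
count_splits <- function(bst, n_trees) {
  d <- xgboost::xgb.dump(bst)
  markers <- grep("^booster", d)
  end <- if (n_trees < length(markers)) markers[n_trees + 1L] - 1L else length(d)
  sum(grepl("yes=", d[seq_len(end)], fixed = TRUE))
}

#' Train one CV fold with validation-AUC early stopping
#'
#' Boosting is monitored on the validation AUC and halts when 50 rounds
#' pass without improvement (or at 500 rounds); the retained model is
#' truncated to the best-validation iteration.
#'
#' @param X_tr,y_tr Training split (active features only).
#' @param X_val,y_val Validation split.
#' @param spec An `eb_model_spec` from [decode_hyperparams()].
#' @return `NULL` for a degenerate fold (single-class training or
#'   validation split); otherwise a list with `pred_prob`, `pred_label`,
#'   `best_iteration`, `total_splits`, `rounds_trained`.
#' @export
train_fold <- function(X_tr, y_tr, X_val, y_val, spec) {
  if (length(unique(y_tr)) < 2L || length(unique(y_val)) < 2L) return(NULL)
  dtr <- xgboost::xgb.DMatrix(X_tr, label = y_tr)
  dval <- xgboost::xgb.DMatrix(X_val, label = y_val)
  params <- c(list(objective = "binary:logistic", eval_metric = "auc",
                   tree_method = "exact", nthread = 1L, seed = 0L),
              spec$params)
  bst <- xgboost::xgb.train(params = params, data = dtr,
                            nrounds = spec$max_rounds,
                            evals = list(val = dval),
                            early_stopping_rounds = spec$patience,
                            verbose = 0)
  log <- attributes(bst)$evaluation_log
  best_iter <- which.max(log$val_auc)
  prob <- stats::predict(bst, X_val, iterationrange = c(1L, best_iter))
  list(pred_prob = prob,
       pred_label = as.integer(prob >= 0.5),
       best_iteration = best_iter,
       total_splits = count_splits(bst, best_iter),
       rounds_trained = nrow(log))
}

#' Evaluate one chromosome under a CV plan
#'
#' Per-fold metrics are averaged arithmetically across folds; pooled
#' out-of-fold predictions are retained for the degenerate filter and
#' ensemble voting. An empty active set scores 0 on every classification
#' objective while the complexity objectives follow their formulas.
#'
#' @param chrom An `eb_chromosome`.
#' @param dataset An `eb_dataset`.
#' @param index An `eb_prescreen`.
#' @param plan An `eb_cv_plan`.
#' @param weights Objective weights for the weighted overall score.
#' @param bounds Hyperparameter bounds.
#' @param s_max Split-complexity budget.
#' @return An `eb_solution`: chromosome, named `objectives` vector,
#'   `overall`, `weighted_overall`, pooled `oof` predictions, `active`
#'   indices, `mean_total_splits`, per-fold `best_iterations`, and the
#'   `degenerate` flag (pooled predictions single-class).
#' @export
evaluate_solution <- function(chrom, dataset, index, plan, weights = NULL,
                              bounds = hyperparam_bounds(), s_max = 256) {
  p <- ncol(dataset$X)
  dec <- decode_features(chrom, index)
  active <- dec$active
  empty_objectives <- function(n_active) {
    obj <- stats::setNames(rep(0, 10L), objective_names())
    obj["feature_complexity"] <- feature_complexity(n_active, p)
    obj["split_complexity"] <- split_complexity(0, s_max)
    obj
  }
  finish <- function(obj, oof, splits, iters, degenerate) {
    sc <- overall_scores(obj, weights)
    structure(
      list(chromosome = chrom, objectives = obj, overall = sc$overall,
           weighted_overall = sc$weighted_overall, oof = oof,
           active = active, n_active = length(active),
           mean_total_splits = splits, best_iterations = iters,
           degenerate = degenerate, key = chromosome_key(chrom)),
      class = "eb_solution"
    )
  }
  if (length(active) == 0L)
    return(finish(empty_objectives(0L), NULL, 0, integer(0), TRUE))

  n_pos <- sum(dataset$y == 1L); n_neg <- sum(dataset$y == 0L)
  w_maj <- max(n_pos, n_neg) / (n_pos + n_neg)
  spec <- decode_hyperparams(chrom, n_pos, n_neg, bounds)
  Xa <- dataset$X[, active, drop = FALSE]
  y <- dataset$y
  n <- length(y)
  oof_prob <- rep(NA_real_, n); oof_label <- rep(NA_integer_, n)
  metric_names <- c("accuracy", "wgm", "f1", "f2", "precision", "recall",
                    "balanced_accuracy", "auc")
  fold_metrics <- list(); splits <- c(); iters <- c()
  for (f in seq_along(plan$folds)) {
    val <- plan$folds[[f]]
    tr <- setdiff(seq_len(n), val)
    res <- train_fold(Xa[tr, , drop = FALSE], y[tr],
                      Xa[val, , drop = FALSE], y[val], spec)
    if (is.null(res)) next
    m <- classification_metrics(y[val], res$pred_label, res$pred_prob,
                                wgm_weight = w_maj)
    fold_metrics[[length(fold_metrics) + 1L]] <- unlist(m[metric_names])
    splits <- c(splits, res$total_splits)
    iters <- c(iters, res$best_iteration)
    oof_prob[val] <- res$pred_prob
    oof_label[val] <- res$pred_label
  }
  if (length(fold_metrics) == 0L)
    return(finish(empty_objectives(length(active)), NULL, 0, integer(0), TRUE))
  cls <- colMeans(do.call(rbind, fold_metrics))
  mean_splits <- mean(splits)
  obj <- stats::setNames(
    c(cls, feature_complexity(length(active), p),
      split_complexity(mean_splits, s_max)),
    objective_names())
  seen <- !is.na(oof_label)
  oof <- list(prob = oof_prob, label = oof_label)
  degenerate <- length(unique(oof_label[seen])) <= 1L
  sol <- finish(obj, oof, mean_splits, iters, degenerate)
  sol
}
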