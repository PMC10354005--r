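# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementations.

# Confusion-matrix metrics from first principles.
oracle_metrics <- function(y_true, y_pred) {
  tp <- sum(y_true == 1 & y_pred == 1); fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0); fp <- sum(y_true == 0 & y_pred == 1)
  div <- function(a, b) if (b == 0) 0 else a / b
  pre <- div(tp, tp + fp); rec <- div(tp, tp + fn); spe <- div(tn, tn + fp)
  list(accuracy = div(tp + tn, length(y_true)), precision = pre, recall = rec,
       specificity = spe, balanced_accuracy = (rec + spe) / 2,
       f1 = div(2 * pre * rec, pre + rec),
       f2 = div((1 + 4) * pre * rec, 4 * pre + rec))
}

# AUC as the brute-force fraction of concordant positive/negative pairs
# (ties count one half).
oracle_auc <- function(y_true, score) {
  pos <- score[y_true == 1]; neg <- score[y_true == 0]
  if (!length(pos) || !length(neg)) return(0)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Pareto fronts by repeated peeling with a quadratic double loop.
oracle_fronts <- function(M) {
  n <- nrow(M)
  dominated_by_any <- function(i, pool) {
    for (j in pool) {
      if (j == i) next
      if (all(M[j, ] >= M[i, ]) && any(M[j, ] > M[i, ])) return(TRUE)
    }
    FALSE
  }
  remaining <- seq_len(n)
  fronts <- list()
  while (length(remaining)) {
    nd <- remaining[!vapply(remaining, dominated_by_any, TRUE,
                            pool = remaining)]
    fronts[[length(fronts) + 1L]] <- sort(nd)
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

# Plug-in MI via the entropy identity H(a) + H(b) - H(a,b), in bits.
oracle_mi <- function(a, b) {
  H <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log2(p))
  }
  H(a) + H(b) - H(paste(a, b))
}

# Brute-force greedy JMI: recompute the full criterion for every
# candidate at every step with oracle_mi.
oracle_jmi <- function(D, y, k) {
  p <- ncol(D)
  sel <- integer(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(p), sel)
    crit <- vapply(cand, function(f) {
      if (!length(sel)) return(oracle_mi(D[, f], y))
      sum(vapply(sel, function(s) oracle_mi(paste(D[, f], D[, s]), y), 0))
    }, 0)
    sel <- c(sel, cand[which.max(crit)])
  }
  sel
}

# Brute-force greedy mRMR with the MID criterion.
oracle_mrmr <- function(D, y, k) {
  p <- ncol(D)
  sel <- integer(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(p), sel)
    crit <- vapply(cand, function(f) {
      rel <- oracle_mi(D[, f], y)
      if (!length(sel)) return(rel)
      rel - mean(vapply(sel, function(s) oracle_mi(D[, f], D[, s]), 0))
    }, 0)
    sel <- c(sel, cand[which.max(crit)])
  }
  sel
}

# Small ready-made dataset builders -----------------------------------

# Direct eb_dataset construction without the preprocessing chain.
tiny_dataset <- function(X, y, names = NULL) {
  colnames(X) <- names %||% sprintf("F%03d", seq_len(ncol(X)))
  structure(list(X = X, y = as.integer(y), feature_names = colnames(X),
                 sample_ids = as.character(seq_len(nrow(X))),
                 positive_label = "1", meta = list()),
            class = "eb_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small noisy two-class dataset with `n_inf` informative features.
small_signal_dataset <- function(n = 60, p = 20, n_inf = 3, effect = 1.5,
                                 seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[y == 1, seq_len(n_inf)] <- X[y == 1, seq_len(n_inf)] + effect
  tiny_dataset(X, y)
}

random_chromosome <- function(p, k_max = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  init_population(p, 2L, k_max = k_max)[[1L]]
}

# Hand-built evaluated solution with constant objectives, for ranking,
# niching and voting tests that need no classifier.
fake_solution <- function(chrom, overall, degenerate = FALSE) {
  obj <- stats::setNames(rep(overall, 10), objective_names())
  structure(list(chromosome = chrom, objectives = obj, overall = overall,
                 weighted_overall = overall, oof = NULL,
                 active = which(chrom$mask), n_active = sum(chrom$mask),
                 mean_total_splits = 0, best_iterations = 1L,
                 degenerate = degenerate,
                 key = evoboost:::chromosome_key(chrom)),
            class = "eb_solution")
}
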