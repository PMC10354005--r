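# Filter prescreens referenced by the chromosomes' FS genes: ANOVA-F
# (SelectKBest style), Wilcoxon rank sums, joint mutual information and
# minimum-redundancy maximum-relevance.

F_SENTINEL <- 1e12  # finite stand-in for an infinite F statistic

#' Per-feature ANOVA F statistic (two-group)
#'
#' One-way ANOVA F per feature; higher means more class separation.
#' Constant features score 0; features with zero within-group variance
#' but non-zero between-group variance are capped at a large finite
#' sentinel.
#'
#' @param X n-by-p numeric matrix.
#' @param y Binary 0/1 vector of length n.
#' @return Numeric vector of p scores.
#' @export
score_kbest <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  i1 <- y == 1L; i0 <- !i1
  n1 <- sum(i1); n0 <- sum(i0)
  stopifnot(n1 >= 1L, n0 >= 1L)
  m1 <- colMeans(X[i1, , drop = FALSE])
  m0 <- colMeans(X[i0, , drop = FALSE])
  gm <- colMeans(X)
  ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  ssw <- colSums((X[i1, , drop = FALSE] - rep(m1, each = n1))^2) +
         colSums((X[i0, , drop = FALSE] - rep(m0, each = n0))^2)
  f <- ssb / (ssw / (n - 2L))
  f[ssw == 0 & ssb > 0] <- F_SENTINEL
  f[ssb == 0] <- 0
  f
}

# Exact conditional rank-sum distribution by enumerating which midranks
# fall in the positive group; valid with ties.
wilcoxon_exact_p <- function(r, n1) {
  W <- utils::combn(r, n1, sum)
  w_obs <- sum(r[seq_len(n1)])  # caller orders positive group first
  p <- 2 * min(mean(W <= w_obs + 1e-9), mean(W >= w_obs - 1e-9))
  min(1, p)
}

#' Per-feature Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test per feature with midrank ties. The exact
#' conditional distribution is enumerated when the number of group
#' assignments is small (at most `exact_limit`); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' Features are ranked by ascending p-value.
#'
#' @inheritParams score_kbest
#' @param exact_limit Enumerate exactly when `choose(n, n1)` does not
#'   exceed this.
#' @return List with `statistic` (positive-group rank sums) and
#'   `p_value` vectors of length p.
#' @export
score_wilcoxon <- function(X, y, exact_limit = 20000) {
  X <- as.matrix(X)
  n <- nrow(X)
  i1 <- which(y == 1L); i0 <- which(y != 1L)
  n1 <- length(i1); n0 <- length(i0)
  stopifnot(n1 >= 1L, n0 >= 1L)
  exact <- choose(n, n1) <= exact_limit
  stat <- p <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    r <- rank(X[, j])
    w <- sum(r[i1])
    stat[j] <- w
    if (exact) {
      p[j] <- wilcoxon_exact_p(c(r[i1], r[i0]), n1)
    } else {
      mu <- n1 * (n + 1) / 2
      ties <- table(r)
      sig2 <- n1 * n0 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
      if (sig2 <= 0) { p[j] <- 1; next }
      z <- (abs(w - mu) - 0.5) / sqrt(sig2)
      p[j] <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
  }
  list(statistic = stat, p_value = p)
}

#' Equal-frequency discretization for information-theoretic filters
#'
#' Continuous features are binned into `min(5, ceiling(sqrt(n)))`
#' equal-frequency bins (fewer when quantiles tie).
#'
#' @param X n-by-p numeric matrix.
#' @param n_bins Optional bin count override.
#' @return Integer matrix of 1-based bin codes with attribute `n_levels`.
#' @export
discretize_features <- function(X, n_bins = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  nb <- n_bins %||% min(5L, ceiling(sqrt(n)))
  D <- matrix(1L, n, ncol(X))
  nlev <- integer(ncol(X))
  for (j in seq_len(ncol(X))) {
    br <- unique(stats::quantile(X[, j], probs = seq_len(nb - 1L) / nb,
                                 names = FALSE, type = 7))
    code <- findInterval(X[, j], br, left.open = TRUE) + 1L
    D[, j] <- match(code, sort(unique(code)))  # compact codes 1..k
    nlev[j] <- max(D[, j])
  }
  attr(D, "n_levels") <- nlev
  D
}

# Plug-in MI in bits from compact 1-based integer codes.
mi_disc <- function(a, b, na = max(a), nb = max(b)) {
  joint <- tabulate(a + na * (b - 1L), na * nb)
  n <- length(a)
  pj <- joint[joint > 0] / n
  pa <- tabulate(a, na) / n
  pb <- tabulate(b, nb) / n
  hj <- -sum(pj * log2(pj))
  ha <- -sum(pa[pa > 0] * log2(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log2(pb[pb > 0]))
  max(0, ha + hb - hj)
}

# Compact an arbitrary discrete vector to 1-based codes.
compact_codes <- function(x) {
  u <- sort(unique(x))
  match(x, u)
}

#' Mutual information between two discrete vectors
#'
#' Plug-in estimate from the joint contingency table, in bits (log base
#' 2). Non-negative; zero iff the empirical joint factorizes.
#'
#' @param a,b Equal-length vectors (integer codes, factors or values
#'   with few distinct levels). Continuous features must be discretized
#'   first, see [discretize_features()].
#' @return Mutual information in bits.
#' @export
mutual_information <- function(a, b) {
  stopifnot(length(a) == length(b))
  ia <- compact_codes(as.vector(a)); ib <- compact_codes(as.vector(b))
  mi_disc(ia, ib)
}

# Shared greedy driver. relevance[j] = I(x_j; y). `gain` computes the
# step criterion for every remaining candidate given the selected set.
greedy_select <- function(p, k, relevance, gain) {
  stopifnot(k >= 1L, k <= p)
  selected <- integer(0)
  remaining <- seq_len(p)
  first <- remaining[which.max(relevance)]  # which.max takes lowest index tie
  selected <- first
  remaining <- setdiff(remaining, first)
  while (length(selected) < k && length(remaining) > 0L) {
    crit <- gain(remaining, selected)
    pick <- remaining[which.max(crit)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

#' Joint-mutual-information feature ranking
#'
#' Greedy forward selection. The first pick maximizes I(f; y); each
#' subsequent pick maximizes the sum over already-selected s of
#' I((f, s); y), the mutual information of the paired variable with the
#' label. Ties break to the lowest feature index.
#'
#' @inheritParams score_kbest
#' @param k Number of features to rank.
#' @param disc Optional pre-discretized matrix from
#'   [discretize_features()].
#' @return Integer vector of k feature indices, best first.
#' @export
select_jmi <- function(X, y, k, disc = NULL) {
  D <- disc %||% discretize_features(X)
  nlev <- attr(D, "n_levels")
  ycode <- compact_codes(y); ny <- max(ycode)
  p <- ncol(D)
  relevance <- vapply(seq_len(p), function(j) mi_disc(D[, j], ycode, nlev[j], ny), 0)
  # cumulative JMI scores, updated when a feature enters the selected set
  cum <- rep(0, p)
  last_added <- NA_integer_
  gain <- function(remaining, selected) {
    s <- selected[length(selected)]
    for (f in remaining) {
      pair <- D[, f] + nlev[f] * (D[, s] - 1L)
      cum[f] <<- cum[f] + mi_disc(compact_codes(pair), ycode, nb = ny)
    }
    cum[remaining]
  }
  greedy_select(p, k, relevance, gain)
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy mutual-information difference (MID) criterion: pick
#' argmax \[ I(f; y) - mean over selected s of I(f; s) \]. The first pick
#' maximizes relevance alone. Ties break to the lowest feature index.
#'
#' @inheritParams select_jmi
#' @return Integer vector of k feature indices, best first.
#' @export
select_mrmr <- function(X, y, k, disc = NULL) {
  D <- disc %||% discretize_features(X)
  nlev <- attr(D, "n_levels")
  ycode <- compact_codes(y); ny <- max(ycode)
  p <- ncol(D)
  relevance <- vapply(seq_len(p), function(j) mi_disc(D[, j], ycode, nlev[j], ny), 0)
  red_sum <- rep(0, p)
  gain <- function(remaining, selected) {
    s <- selected[length(selected)]
    for (f in remaining)
      red_sum[f] <<- red_sum[f] + mi_disc(D[, f], D[, s], nlev[f], nlev[s])
    relevance[remaining] - red_sum[remaining] / length(selected)
  }
  greedy_select(p, k, relevance, gain)
}

#' Build the prescreen index used by FS genes
#'
#' Computes, once before generation 0: full ANOVA-F and Wilcoxon
#' rankings, and greedy JMI and mRMR orderings of length `k_max`. All
#' four are deterministic given the dataset.
#'
#' @param dataset An `eb_dataset`.
#' @param k_max Length of the greedy JMI/mRMR orderings (capped at p).
#' @return An `eb_prescreen` object: per-method ordered index vectors
#'   (best first) plus scores and the discretization used.
#' @export
build_prescreen_index <- function(dataset, k_max = 50L) {
  stopifnot(inherits(dataset, "eb_dataset"))
  X <- dataset$X; y <- dataset$y
  p <- ncol(X)
  k_max <- min(as.integer(k_max), p)
  fs <- score_kbest(X, y)
  wx <- score_wilcoxon(X, y)
  disc <- discretize_features(X)
  structure(
    list(
      p = p, k_max = k_max, checksum = dataset_checksum(dataset),
      rankings = list(
        kbest = order(-fs, seq_len(p)),
        wilcoxon = order(wx$p_value, seq_len(p)),
        jmi = select_jmi(X, y, k_max, disc = disc),
        mrmr = select_mrmr(X, y, k_max, disc = disc)
      ),
      scores = list(kbest = fs, wilcoxon_p = wx$p_value),
      n_bins = max(attr(disc, "n_levels"))
    ),
    class = "eb_prescreen"
  )
}

#' Content checksum of a dataset
#'
#' Cheap deterministic fingerprint (dimensions, matrix moments, label
#' sum) used to key cached prescreen indices to the dataset they were
#' built on.
#'
#' @param dataset An `eb_dataset`.
#' @return Character scalar.
#' @export
dataset_checksum <- function(dataset) {
  sprintf("%dx%d|%.12e|%.12e|%d", nrow(dataset$X), ncol(dataset$X),
          sum(dataset$X), sum(dataset$X^2), sum(dataset$y))
}

#' Serialize / restore a prescreen index
#'
#' The cache is keyed by a content checksum of the dataset; reading
#' with `dataset` supplied fails if the cache was built on different
#' data.
#'
#' @param index An `eb_prescreen`.
#' @param path JSON file path.
#' @param dataset Optional `eb_dataset` to verify the cache against.
#' @return `write_prescreen_index` invisibly returns `path`;
#'   `read_prescreen_index` returns the restored `eb_prescreen`.
#' @export
write_prescreen_index <- function(index, path) {
  jsonlite::write_json(unclass(index), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prescreen_index
#' @export
read_prescreen_index <- function(path, dataset = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$rankings <- lapply(obj$rankings, as.integer)
  if (!is.null(dataset) && !identical(obj$checksum, dataset_checksum(dataset)))
    stopf("prescreen cache at '%s' was built on different data", path)
  structure(obj, class = "eb_prescreen")
}
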