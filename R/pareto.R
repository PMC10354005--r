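# Nondominated sorting and fitness sharing on the dual genotype
# distance (parameter genes + feature mask).

#' Pareto dominance of objective vectors
#'
#' `u` dominates `v` when every component of `u` is at least as large
#' and at least one is strictly larger (all objectives maximized).
#'
#' @param u,v Numeric objective vectors of equal length.
#' @return Logical.
#' @export
dominates <- function(u, v) {
  all(u >= v) && any(u > v)
}

#' Fast nondominated sorting
#'
#' Ranks rows of an objective matrix into Pareto fronts (front 1 is the
#' dominant set). Within-front order is stable by input index.
#'
#' @param objectives Numeric matrix, one row per solution.
#' @return List with `fronts` (list of index vectors) and `front_index`
#'   (1-based front number per solution).
#' @export
nondominated_sort <- function(objectives) {
  M <- as.matrix(objectives)
  n <- nrow(M)
  stopifnot(n >= 1L)
  # D[i, j] = TRUE iff i dominates j
  D <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    diff <- M - matrix(M[j, ], n, ncol(M), byrow = TRUE)
    D[, j] <- rowSums(diff >= 0) == ncol(M) & rowSums(diff > 0) > 0
  }
  n_dom <- colSums(D)           # how many dominate j
  front_index <- integer(n)
  fronts <- list()
  current <- which(n_dom == 0L)
  f <- 0L
  remaining <- rep(TRUE, n)
  while (length(current) > 0L) {
    f <- f + 1L
    fronts[[f]] <- sort(current)
    front_index[current] <- f
    remaining[current] <- FALSE
    for (i in current) n_dom <- n_dom - D[i, ]
    current <- which(remaining & n_dom == 0L)
  }
  list(fronts = fronts, front_index = front_index)
}

#' Dual chromosome distance
#'
#' `0.5 * d_params + 0.5 * d_mask`, where `d_params` averages the
#' normalized absolute differences of the seven hyperparameter genes,
#' the FS-method mismatch indicator and the fs_k difference normalized
#' by `k_max`, and `d_mask` is the Jaccard distance of the active-bit
#' sets (0 when both masks are empty). Symmetric, bounded in \[0, 1\],
#' zero on identical chromosomes.
#'
#' @param a,b `eb_chromosome`s on the same feature space.
#' @param bounds Hyperparameter bounds.
#' @param k_max fs_k normalization constant.
#' @return Distance in \[0, 1\].
#' @export
chromosome_distance <- function(a, b, bounds = hyperparam_bounds(),
                                k_max = 50L) {
  rg <- bounds$upper - bounds$lower
  d_hyper <- abs(a$hyper - b$hyper) / rg
  d_fs <- as.numeric(a$fs_method != b$fs_method)
  d_k <- abs(a$fs_k - b$fs_k) / k_max
  d_params <- mean(c(d_hyper, d_fs, d_k))
  ua <- which(a$mask); ub <- which(b$mask)
  uni <- length(union(ua, ub))
  d_mask <- if (uni == 0L) 0 else 1 - length(intersect(ua, ub)) / uni
  0.5 * d_params + 0.5 * d_mask
}

#' Fitness sharing within a Pareto front
#'
#' Triangular sharing kernel `sh(d) = 1 - d/sigma` for `d < sigma`, else
#' 0. Each solution's niche count sums the kernel over the whole front
#' (including itself, so counts are at least 1) and its niched score is
#' `overall / niche_count`. Sharing never raises a score and never
#' changes front membership.
#'
#' @param front List of `eb_solution`s belonging to one front.
#' @param sigma_share Kernel support (default 0.2).
#' @param bounds Hyperparameter bounds.
#' @param k_max fs_k normalization constant.
#' @return List with `niche_count` and `niched_score` vectors.
#' @export
niche_degrade <- function(front, sigma_share = 0.2,
                          bounds = hyperparam_bounds(), k_max = 50L) {
  m <- length(front)
  counts <- rep(1, m)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        d <- chromosome_distance(front[[i]]$chromosome,
                                 front[[j]]$chromosome, bounds, k_max)
        if (d < sigma_share) {
          sh <- 1 - d / sigma_share
          counts[i] <- counts[i] + sh
          counts[j] <- counts[j] + sh
        }
      }
    }
  }
  overall <- vapply(front, function(s) s$overall, 0)
  list(niche_count = counts, niched_score = overall / counts)
}

#' Rank a population into niched Pareto fronts
#'
#' @param solutions List of `eb_solution`s.
#' @param sigma_share Sharing kernel support.
#' @param bounds Hyperparameter bounds.
#' @param k_max fs_k normalization constant.
#' @return An `eb_ranking`: `front_index`, `niche_count`, `niched_score`
#'   per solution, plus the `fronts` index list.
#' @export
pareto_rank <- function(solutions, sigma_share = 0.2,
                        bounds = hyperparam_bounds(), k_max = 50L) {
  M <- do.call(rbind, lapply(solutions, function(s) s$objectives))
  srt <- nondominated_sort(M)
  niche_count <- numeric(length(solutions))
  niched_score <- numeric(length(solutions))
  for (fr in srt$fronts) {
    nd <- niche_degrade(solutions[fr], sigma_share, bounds, k_max)
    niche_count[fr] <- nd$niche_count
    niched_score[fr] <- nd$niched_score
  }
  structure(
    list(front_index = srt$front_index, fronts = srt$fronts,
         niche_count = niche_count, niched_score = niched_score),
    class = "eb_ranking"
  )
}

#' Per-front summary report
#'
#' @param solutions List of `eb_solution`s.
#' @param ranking Their `eb_ranking`.
#' @return List (one entry per front) with size, niche counts and the
#'   best overall score, suitable for JSON export.
#' @export
front_report <- function(solutions, ranking) {
  lapply(seq_along(ranking$fronts), function(f) {
    idx <- ranking$fronts[[f]]
    list(front = f, size = length(idx),
         best_overall = max(vapply(solutions[idx], function(s) s$overall, 0)),
         niche_counts = ranking$niche_count[idx])
  })
}
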