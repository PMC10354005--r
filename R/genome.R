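# The hybrid genotype: binary feature mask + FS genes + seven classifier
# hyperparameter genes, with uniform initialization, uniform crossover
# and bounded Gaussian/bit-flip mutation.

FS_METHODS <- c("none", "kbest", "wilcoxon", "jmi", "mrmr")

#' Bounds of the seven classifier hyperparameter genes
#'
#' Learning rate, tree depth, two pruning parameters (minimum split
#' loss, minimum child weight), two generalization parameters (L2 and
#' L1 regularization) and a balancing parameter (a multiplier on the
#' negatives/positives ratio used as the positive-class weight).
#'
#' @return Data frame with columns `name`, `lower`, `upper`, `integer`.
#' @export
hyperparam_bounds <- function() {
  data.frame(
    name = c("learning_rate", "max_depth", "min_split_loss",
             "min_child_weight", "l2_regularization", "l1_regularization",
             "positive_class_weight"),
    lower = c(0.01, 1, 0, 1, 0, 0, 0.1),
    upper = c(0.5, 10, 5, 10, 10, 5, 10),
    integer = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

validate_chromosome <- function(chrom, bounds = hyperparam_bounds()) {
  stopifnot(inherits(chrom, "eb_chromosome"))
  h <- chrom$hyper
  assert_that(length(h) == nrow(bounds), "expected %d hyperparameter genes",
              nrow(bounds))
  assert_that(all(h >= bounds$lower - 1e-12) && all(h <= bounds$upper + 1e-12),
              "hyperparameter gene out of bounds")
  assert_that(all(h[bounds$integer] == round(h[bounds$integer])),
              "integer gene not integral")
  assert_that(chrom$fs_method %in% FS_METHODS, "unknown fs_method")
  assert_that(chrom$fs_k >= 1L, "fs_k must be >= 1")
  assert_that(is.logical(chrom$mask), "mask must be logical")
  invisible(chrom)
}

new_chromosome <- function(mask, fs_method, fs_k, hyper,
                           bounds = hyperparam_bounds()) {
  names(hyper) <- bounds$name
  chrom <- structure(
    list(mask = as.logical(mask), fs_method = fs_method,
         fs_k = as.integer(fs_k), hyper = hyper),
    class = "eb_chromosome"
  )
  validate_chromosome(chrom, bounds)
}

# Canonical key for deterministic tie-breaking and caching.
chromosome_key <- function(chrom) {
  paste(chrom$fs_method, chrom$fs_k,
        paste(sprintf("%.12g", chrom$hyper), collapse = ","),
        paste(which(chrom$mask), collapse = "."), sep = "|")
}

#' Initialize a pseudorandom population
#'
#' Hyperparameters are drawn uniformly within their bounds (integer
#' genes uniformly over the integer range). Each feature mask activates
#' m bits, m uniform on 1..29 (capped at p), at uniformly drawn
#' positions; the FS-method gene is uniform over the five options and
#' fs_k uniform on 1..`k_max`.
#'
#' @param p Number of features.
#' @param size Population size (at least 2).
#' @param bounds Hyperparameter bounds, see [hyperparam_bounds()].
#' @param k_max Upper bound of the fs_k gene.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return List of `eb_chromosome`.
#' @export
init_population <- function(p, size, bounds = hyperparam_bounds(),
                            k_max = 50L, seed = NULL) {
  stopifnot(size >= 2L, p >= 1L)
  draw <- function() {
    hyper <- numeric(nrow(bounds))
    for (g in seq_len(nrow(bounds))) {
      hyper[g] <- if (bounds$integer[g])
        sample(bounds$lower[g]:bounds$upper[g], 1L)
      else stats::runif(1L, bounds$lower[g], bounds$upper[g])
    }
    m <- sample.int(min(29L, p), 1L)
    mask <- rep(FALSE, p)
    mask[sample.int(p, m)] <- TRUE
    new_chromosome(mask, sample(FS_METHODS, 1L), sample.int(k_max, 1L),
                   hyper, bounds)
  }
  gen <- function() replicate(size, draw(), simplify = FALSE)
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Decode the active feature set of a chromosome
#'
#' With `fs_method = "none"` the active set is the mask's set bits.
#' Otherwise the mask is intersected with the top-`fs_k` features of the
#' chosen prescreen list (`fs_k` interpreted modulo the list length); an
#' empty intersection falls back to the raw mask bits. An empty mask is
#' flagged degenerate.
#'
#' @param chrom An `eb_chromosome`.
#' @param index An `eb_prescreen` built on the same feature space.
#' @return List with `active` (sorted indices), `degenerate`, `fallback`.
#' @export
decode_features <- function(chrom, index) {
  mask_idx <- which(chrom$mask)
  if (length(mask_idx) == 0L)
    return(list(active = integer(0), degenerate = TRUE, fallback = FALSE))
  if (chrom$fs_method == "none")
    return(list(active = mask_idx, degenerate = FALSE, fallback = FALSE))
  lst <- index$rankings[[chrom$fs_method]]
  k_eff <- ((chrom$fs_k - 1L) %% length(lst)) + 1L
  act <- intersect(mask_idx, lst[seq_len(k_eff)])
  if (length(act) == 0L)
    list(active = mask_idx, degenerate = FALSE, fallback = TRUE)
  else
    list(active = sort(act), degenerate = FALSE, fallback = FALSE)
}

#' Decode the classifier configuration of a chromosome
#'
#' Maps the seven genes onto the boosted-tree configuration. The
#' balancing gene multiplies the dataset's negatives/positives ratio to
#' give the effective positive-class weight. The boosting budget is 500
#' rounds with an early-stopping patience of 50.
#'
#' @param chrom An `eb_chromosome`.
#' @param n_pos,n_neg Class counts of the training data.
#' @param bounds Hyperparameter bounds.
#' @return An `eb_model_spec`: `params` (named list for the booster),
#'   `max_rounds`, `patience`.
#' @export
decode_hyperparams <- function(chrom, n_pos, n_neg,
                               bounds = hyperparam_bounds()) {
  h <- chrom$hyper
  structure(
    list(
      params = list(
        eta = unname(h["learning_rate"]),
        max_depth = as.integer(h["max_depth"]),
        gamma = unname(h["min_split_loss"]),
        min_child_weight = unname(h["min_child_weight"]),
        lambda = unname(h["l2_regularization"]),
        alpha = unname(h["l1_regularization"]),
        scale_pos_weight = unname(h["positive_class_weight"]) * n_neg / n_pos
      ),
      max_rounds = 500L, patience = 50L
    ),
    class = "eb_model_spec"
  )
}

#' Uniform crossover
#'
#' Each mask bit and each parameter/FS gene is inherited from parent `a`
#' with probability 0.5 (the sibling takes the other parent's gene).
#'
#' @param a,b Parent `eb_chromosome`s on the same feature space.
#' @param bounds Hyperparameter bounds.
#' @return List of two child chromosomes.
#' @export
crossover <- function(a, b, bounds = hyperparam_bounds()) {
  stopifnot(length(a$mask) == length(b$mask))
  take_a_mask <- stats::runif(length(a$mask)) < 0.5
  take_a_gene <- stats::runif(nrow(bounds) + 2L) < 0.5
  child <- function(first, second, ta_mask, ta_gene) {
    mask <- ifelse(ta_mask, first$mask, second$mask)
    hyper <- ifelse(ta_gene[seq_len(nrow(bounds))], first$hyper, second$hyper)
    fs_method <- if (ta_gene[nrow(bounds) + 1L]) first$fs_method else second$fs_method
    fs_k <- if (ta_gene[nrow(bounds) + 2L]) first$fs_k else second$fs_k
    new_chromosome(mask, fs_method, fs_k, hyper, bounds)
  }
  list(child(a, b, take_a_mask, take_a_gene),
       child(b, a, take_a_mask, take_a_gene))
}

#' Default mutation rates
#'
#' @param p Number of features.
#' @return List with `bit` (per-mask-bit flip probability,
#'   `max(1/p, 0.001)`), `param` (per-gene perturbation probability,
#'   0.2) and `fs` (FS-method resampling probability, 0.05).
#' @export
mutation_rates <- function(p) {
  list(bit = max(1 / p, 0.001), param = 0.2, fs = 0.05)
}

#' Mutate a chromosome
#'
#' Each mask bit flips with probability `rates$bit`; each parameter gene
#' is perturbed, with probability `rates$param`, by Gaussian noise with
#' standard deviation 10% of its range and clipped to bounds (integer
#' genes re-rounded); the FS-method gene is resampled with probability
#' `rates$fs`; fs_k is treated as an integer parameter gene on
#' 1..`k_max`.
#'
#' @param chrom An `eb_chromosome`.
#' @param rates See [mutation_rates()].
#' @param bounds Hyperparameter bounds.
#' @param k_max Upper bound of fs_k.
#' @return The mutated chromosome.
#' @export
mutate <- function(chrom, rates = NULL, bounds = hyperparam_bounds(),
                   k_max = 50L) {
  p <- length(chrom$mask)
  rates <- rates %||% mutation_rates(p)
  flip <- stats::runif(p) < rates$bit
  mask <- xor(chrom$mask, flip)
  hyper <- chrom$hyper
  for (g in seq_along(hyper)) {
    if (stats::runif(1L) < rates$param) {
      rg <- bounds$upper[g] - bounds$lower[g]
      v <- hyper[g] + stats::rnorm(1L, 0, 0.1 * rg)
      v <- min(max(v, bounds$lower[g]), bounds$upper[g])
      hyper[g] <- if (bounds$integer[g]) round(v) else v
    }
  }
  fs_method <- chrom$fs_method
  if (stats::runif(1L) < rates$fs) fs_method <- sample(FS_METHODS, 1L)
  fs_k <- chrom$fs_k
  if (stats::runif(1L) < rates$param) {
    v <- round(fs_k + stats::rnorm(1L, 0, 0.1 * (k_max - 1L)))
    fs_k <- min(max(v, 1L), k_max)
  }
  new_chromosome(mask, fs_method, fs_k, hyper, bounds)
}

#' Serialize chromosomes to and from plain lists
#'
#' The mask is stored as a list of active indices so Pareto-front
#' solutions can be exported as JSON and re-loaded for prediction.
#'
#' @param chrom An `eb_chromosome`.
#' @param p Feature-space size (needed to rebuild the mask).
#' @param lst A list produced by `chromosome_to_list`.
#' @param bounds Hyperparameter bounds.
#' @return A plain list, or the rebuilt `eb_chromosome`.
#' @export
chromosome_to_list <- function(chrom) {
  list(active_bits = which(chrom$mask), p = length(chrom$mask),
       fs_method = chrom$fs_method, fs_k = chrom$fs_k,
       hyper = as.list(chrom$hyper))
}

#' @rdname chromosome_to_list
#' @export
chromosome_from_list <- function(lst, p = lst$p,
                                 bounds = hyperparam_bounds()) {
  mask <- rep(FALSE, p)
  mask[as.integer(unlist(lst$active_bits))] <- TRUE
  new_chromosome(mask, lst$fs_method, lst$fs_k,
                 unlist(lst$hyper)[bounds$name], bounds)
}
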