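# Internal helpers shared across modules.

#' Names and order of the ten maximized objectives
#'
#' Eight classification metrics followed by the two model-simplicity
#' metrics. Every objective lies in \[0, 1\] and is maximized.
#'
#' @return Character vector of length 10.
#' @export
objective_names <- function() {
  c("accuracy", "wgm", "f1", "f2", "precision", "recall",
    "balanced_accuracy", "auc", "feature_complexity", "split_complexity")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded subcomponents (CV plans, fixtures) do not
# perturb the evolutionary random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) if (!isTRUE(cond)) stopf(...)
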