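# Turning the final dominant front into deployable predictors: the
# best-compromise model plus hard and soft majority-voting ensembles
# with degenerate-model exclusion.

#' Exclude degenerate front members
#'
#' Removes every solution whose pooled out-of-fold predictions were
#' single-class; such models reached the front on simplicity alone and
#' add no discrimination to a vote.
#'
#' @param front0 List of `eb_solution`s from the dominant front.
#' @return The surviving solutions; empty input or all-degenerate input
#'   returns an empty list (callers fall back to the best single model).
#' @export
filter_degenerate <- function(front0) {
  Filter(function(s) !isTRUE(s$degenerate), front0)
}

#' Hard majority voting
#'
#' Per sample, the label with the most member votes wins; ties go to the
#' vote of the member with the highest overall score.
#'
#' @param member_labels Members-by-samples 0/1 matrix (one row per
#'   member).
#' @param overall_scores Overall score per member (tie-break).
#' @return Integer 0/1 label vector.
#' @export
hard_vote <- function(member_labels, overall_scores) {
  L <- rbind(member_labels)
  stopifnot(nrow(L) >= 1L, nrow(L) == length(overall_scores))
  ones <- colSums(L == 1L)
  zeros <- colSums(L == 0L)
  best <- which.max(overall_scores)
  out <- integer(ncol(L))
  out[ones > zeros] <- 1L
  tie <- ones == zeros
  out[tie] <- as.integer(L[best, tie])
  out
}

#' Soft majority voting
#'
#' Pools member positive-class probabilities by their unweighted mean;
#' the label is 1 iff the pooled probability is at least 0.5.
#'
#' @param member_probs Members-by-samples probability matrix.
#' @return List with `prob` (pooled probabilities) and `label`.
#' @export
soft_vote <- function(member_probs) {
  P <- rbind(member_probs)
  stopifnot(all(P >= 0 & P <= 1))
  pooled <- colMeans(P)
  list(prob = pooled, label = as.integer(pooled >= 0.5))
}

refit_solution <- function(sol, dataset, config) {
  n_pos <- sum(dataset$y == 1L); n_neg <- sum(dataset$y == 0L)
  spec <- decode_hyperparams(sol$chromosome, n_pos, n_neg, config$bounds)
  rounds <- max(1L, as.integer(round(stats::median(sol$best_iterations))))
  X <- dataset$X[, sol$active, drop = FALSE]
  bst <- xgboost::xgb.train(
    params = c(list(objective = "binary:logistic", tree_method = "exact",
                    nthread = 1L, seed = 0L),
               spec$params),
    data = xgboost::xgb.DMatrix(X, label = dataset$y),
    nrounds = rounds, verbose = 0)
  structure(
    list(booster = bst, active = sol$active,
         feature_names = dataset$feature_names[sol$active],
         overall = sol$overall, objectives = sol$objectives,
         chromosome = sol$chromosome, rounds = rounds,
         degenerate = sol$degenerate),
    class = "eb_model"
  )
}

#' Predict with a refit front model
#'
#' @param object An `eb_model` from [finalize_ensemble()].
#' @param newdata Matrix or data.frame on the full preprocessed feature
#'   space (columns as in the training dataset).
#' @param ... Unused.
#' @return List with `prob` and `label`.
#' @export
predict.eb_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$active, drop = FALSE]
  prob <- stats::predict(object$booster, X)
  list(prob = prob, label = as.integer(prob >= 0.5))
}

#' Predict with a majority-voting ensemble
#'
#' @param object An `eb_ensemble` from [finalize_ensemble()].
#' @param newdata Matrix or data.frame on the full preprocessed feature
#'   space.
#' @param ... Unused.
#' @return List with `label` and, for soft voting, pooled `prob`.
#' @export
predict.eb_ensemble <- function(object, newdata, ...) {
  preds <- lapply(object$members, stats::predict, newdata = newdata)
  probs <- do.call(rbind, lapply(preds, `[[`, "prob"))
  labels <- do.call(rbind, lapply(preds, `[[`, "label"))
  if (object$voting == "soft") {
    soft_vote(probs)
  } else {
    list(label = hard_vote(labels,
                           vapply(object$members, function(m) m$overall, 0)))
  }
}

#' Finalize a run into deployable models
#'
#' Recovers the final first front, excludes degenerate members (falling
#' back to the best-overall model, with a warning, if the filter empties
#' the front), refits each survivor on the full dataset with its median
#' best-iteration boosting budget, and returns the best-compromise
#' model, hard and soft voting ensembles and the best model's selected
#' feature names (the biosignature).
#'
#' @param run An `eb_run`.
#' @param dataset The `eb_dataset` the run was trained on.
#' @return An `eb_final`: `best_model` (`eb_model`), `hard_ensemble`
#'   and `soft_ensemble` (`eb_ensemble`), `biosignature` (character
#'   vector), `front0_size`, `n_excluded`.
#' @export
finalize_ensemble <- function(run, dataset) {
  stopifnot(inherits(run, "eb_run"), inherits(dataset, "eb_dataset"))
  front0 <- run$front0
  stopifnot(length(front0) >= 1L)
  overalls <- vapply(front0, function(s) s$overall, 0)
  best_sol <- front0[[which.max(overalls)]]
  members_sol <- filter_degenerate(front0)
  if (length(members_sol) == 0L) {
    warning("all dominant-front models are degenerate; ",
            "falling back to the best-overall model")
    members_sol <- list(best_sol)
  }
  members <- lapply(members_sol, refit_solution, dataset = dataset,
                    config = run$config)
  best_model <- refit_solution(best_sol, dataset, run$config)
  make_ens <- function(mode) structure(
    list(members = members, voting = mode,
         tie_rule = if (mode == "hard") "highest-overall member" else ">= 0.5"),
    class = "eb_ensemble")
  structure(
    list(best_model = best_model,
         hard_ensemble = make_ens("hard"),
         soft_ensemble = make_ens("soft"),
         biosignature = best_model$feature_names,
         front0_size = length(front0),
         n_excluded = length(front0) - length(members_sol)),
    class = "eb_final"
  )
}

#' Save and restore a finalized model bundle
#'
#' Boosters are serialized to raw bytes so the bundle survives an RDS
#' round trip and can be reloaded for prediction in a fresh session.
#'
#' @param final An `eb_final` from [finalize_ensemble()].
#' @param path Bundle file path (RDS).
#' @return `save_model_bundle` invisibly returns `path`;
#'   `load_model_bundle` returns the restored `eb_final`.
#' @export
save_model_bundle <- function(final, path) {
  stopifnot(inherits(final, "eb_final"))
  strip <- function(m) {
    m$booster_raw <- xgboost::xgb.save.raw(m$booster)
    m$booster <- NULL
    m
  }
  out <- final
  out$best_model <- strip(final$best_model)
  out$hard_ensemble$members <- lapply(final$hard_ensemble$members, strip)
  out$soft_ensemble$members <- out$hard_ensemble$members
  saveRDS(out, path)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  final <- readRDS(path)
  revive <- function(m) {
    m$booster <- xgboost::xgb.load.raw(m$booster_raw)
    m$booster_raw <- NULL
    m
  }
  final$best_model <- revive(final$best_model)
  final$hard_ensemble$members <- lapply(final$hard_ensemble$members, revive)
  final$soft_ensemble$members <- final$hard_ensemble$members
  final
}

#' Write the biosignature table
#'
#' Two-column TSV: feature name and a flag string naming the prescreen
#' methods whose top-`k_max` list contains the feature.
#'
#' @param final An `eb_final`.
#' @param run The `eb_run` it came from.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_biosignature <- function(final, run, path) {
  idx <- run$index
  best <- final$best_model
  flags <- vapply(best$active, function(j) {
    inlist <- vapply(idx$rankings, function(r)
      j %in% utils::head(r, idx$k_max), TRUE)
    paste(names(inlist)[inlist], collapse = ",")
  }, "")
  utils::write.table(
    data.frame(feature = best$feature_names, selected_by = flags),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
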