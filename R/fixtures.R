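# Synthetic cohorts with the statistical structure the wrapper assumes:
# few weakly-informative features hidden in noise, correlated duplicates,
# class imbalance, optional missingness and nominal columns.

#' Specify a synthetic cohort
#'
#' @param n_samples Number of samples.
#' @param n_features Total number of feature columns.
#' @param n_informative Number of planted informative features.
#' @param effect_size Standardized mean shift of informative features in
#'   the positive class.
#' @param class_balance Positive-class fraction (positives = round of
#'   `n_samples * class_balance`).
#' @param n_redundant_duplicates Number of noisy copies of informative
#'   features.
#' @param duplicate_cor Target correlation between a duplicate and its
#'   source feature.
#' @param missing_rate Fraction of feature cells set missing completely
#'   at random.
#' @param nominal_fraction Fraction of feature columns converted to
#'   labelled ordinal categories by quantile binning.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A validated `eb_fixture_spec`.
#' @export
fixture_spec <- function(n_samples, n_features, n_informative,
                         effect_size = 1, class_balance = 0.5,
                         n_redundant_duplicates = 0L, duplicate_cor = 0.9,
                         missing_rate = 0, nominal_fraction = 0, seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples),
               n_features = as.integer(n_features),
               n_informative = as.integer(n_informative),
               effect_size = effect_size, class_balance = class_balance,
               n_redundant_duplicates = as.integer(n_redundant_duplicates),
               duplicate_cor = duplicate_cor, missing_rate = missing_rate,
               nominal_fraction = nominal_fraction, seed = as.integer(seed))
  with(spec, {
    assert_that(n_informative + n_redundant_duplicates <= n_features,
                "informative + duplicate features exceed n_features")
    assert_that(missing_rate >= 0 && missing_rate <= 1, "missing_rate in [0,1]")
    assert_that(nominal_fraction >= 0 && nominal_fraction <= 1,
                "nominal_fraction in [0,1]")
    assert_that(class_balance > 0 && class_balance < 1,
                "class_balance in (0,1)")
    assert_that(duplicate_cor > 0 && duplicate_cor <= 1,
                "duplicate_cor in (0,1]")
  })
  structure(spec, class = "eb_fixture_spec")
}

#' Generate a synthetic cohort
#'
#' Noise features are standard normal; informative features are shifted
#' by `effect_size` in the positive class; duplicates are informative
#' features plus independent noise scaled so that the correlation with
#' their source is about `duplicate_cor`. Missingness is completely at
#' random; nominal columns are produced by quartile binning into labelled
#' categories ("q1".."q4"). Positive samples are labelled `"case"`,
#' negatives `"control"`.
#'
#' @param spec An `eb_fixture_spec`.
#' @return A list with `table` (raw data.frame including the `label`
#'   column, possibly with missing cells and nominal columns), `dataset`
#'   (the preprocessed `eb_dataset`), `informative` and `duplicates`
#'   (ground-truth column indices into the dataset), and `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "eb_fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples; p <- spec$n_features
    n_pos <- max(1L, min(n - 1L, round(n * spec$class_balance)))
    y <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    X <- matrix(stats::rnorm(n * p), n, p)
    ninf <- spec$n_informative
    if (ninf > 0L)
      X[y == 1L, seq_len(ninf)] <- X[y == 1L, seq_len(ninf)] + spec$effect_size
    ndup <- spec$n_redundant_duplicates
    if (ndup > 0L) {
      tau <- sqrt(1 / spec$duplicate_cor^2 - 1)
      src <- rep_len(seq_len(ninf), ndup)
      for (d in seq_len(ndup))
        X[, ninf + d] <- X[, src[d]] + tau * stats::rnorm(n)
    }
    perm <- sample.int(p)                      # hide the planted block
    X <- X[, perm, drop = FALSE]
    informative <- match(seq_len(ninf), perm)
    duplicates <- if (ndup > 0L) match(ninf + seq_len(ndup), perm) else integer(0)
    colnames(X) <- sprintf("F%04d", seq_len(p))
    df <- as.data.frame(X, check.names = FALSE)
    n_nom <- floor(spec$nominal_fraction * p)
    if (n_nom > 0L) {
      nom_cols <- sample.int(p, n_nom)
      for (j in nom_cols) {
        q <- stats::quantile(X[, j], c(0.25, 0.5, 0.75), names = FALSE)
        df[[j]] <- paste0("q", findInterval(X[, j], q) + 1L)
      }
    }
    if (spec$missing_rate > 0) {
      holes <- which(stats::runif(n * p) < spec$missing_rate)
      for (h in holes) df[[((h - 1L) %/% n) + 1L]][((h - 1L) %% n) + 1L] <- NA
    }
    df$label <- ifelse(y == 1L, "case", "control")
    raw <- as_raw_table(df, "label")
    dataset <- preprocess_table(raw, positive_label = "case")
    list(table = df, dataset = dataset, informative = sort(informative),
         duplicates = sort(duplicates), spec = spec)
  })
}

#' Expression-like cohort preset
#'
#' Emulates a small blood-transcriptome weight-loss cohort: 89 samples
#' (35 positives, 54 negatives), a few weakly informative genes among
#' thousands of noise genes, and correlated redundant copies. The feature
#' count is scaled to 2000 so full runs complete on a desktop.
#'
#' @param seed Integer seed.
#' @param n_features Number of feature columns (default 2000).
#' @return See [generate_fixture()].
#' @export
make_expression_like <- function(seed = 1L, n_features = 2000L) {
  generate_fixture(fixture_spec(
    n_samples = 89L, n_features = n_features, n_informative = 5L,
    effect_size = 1.0, class_balance = 35 / 89,
    n_redundant_duplicates = 10L, duplicate_cor = 0.9, seed = seed))
}

#' Questionnaire-like cohort preset
#'
#' Emulates a clinical questionnaire table: 631 samples with a 1:9
#' class imbalance over 50 features, 40% of them ordinal categories,
#' 5% missing cells, and 6 weakly informative features.
#'
#' @param seed Integer seed.
#' @return See [generate_fixture()].
#' @export
make_questionnaire_like <- function(seed = 1L) {
  generate_fixture(fixture_spec(
    n_samples = 631L, n_features = 50L, n_informative = 6L,
    effect_size = 0.7, class_balance = 0.1,
    missing_rate = 0.05, nominal_fraction = 0.4, seed = seed))
}

#' Write a fixture to disk
#'
#' Writes the raw table as CSV plus a ground-truth JSON sidecar naming
#' the planted informative and duplicate columns.
#'
#' @param fixture Result of [generate_fixture()].
#' @param path Output CSV path; the sidecar gets the extension
#'   `.truth.json`.
#' @return Invisibly, the two paths written.
#' @export
write_fixture <- function(fixture, path) {
  utils::write.csv(fixture$table, path, row.names = FALSE, na = "")
  sidecar <- paste0(sub("\\.csv$", "", path), ".truth.json")
  jsonlite::write_json(
    list(informative = fixture$dataset$feature_names[fixture$informative],
         duplicates = fixture$dataset$feature_names[fixture$duplicates],
         spec = unclass(fixture$spec)),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(path, sidecar))
}
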