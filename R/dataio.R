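# Tabular input and the four-step preprocessing chain: nominal encoding,
# imputation, normalization, duplicate-feature merging.

MISSING_MARKERS <- c("", "na", "nan", "null")

new_raw_table <- function(features, labels, sample_ids, label_column,
                          meta = list()) {
  structure(
    list(features = features, labels = labels, sample_ids = sample_ids,
         label_column = label_column, meta = meta),
    class = "eb_raw"
  )
}

parse_cell_column <- function(x) {
  x <- as.character(x)
  x[trimws(tolower(x)) %in% MISSING_MARKERS | is.na(x)] <- NA_character_
  num <- suppressWarnings(as.numeric(x))
  if (all(is.na(num) == is.na(x))) num else x
}

#' Build a raw table from an in-memory data frame
#'
#' Cells are typed numeric where the whole column parses as numeric;
#' missing markers (empty string, "NA", "NaN", "nan", "null",
#' case-insensitive) are flagged missing. The label column must hold
#' exactly two distinct non-missing values.
#'
#' @param df data.frame with samples in rows, one column per feature plus
#'   the label column.
#' @param label_column Name of the binary outcome column.
#' @param sample_ids Optional character vector of sample identifiers;
#'   defaults to the data frame's row names.
#' @return An object of class `eb_raw`.
#' @export
as_raw_table <- function(df, label_column, sample_ids = NULL) {
  if (!label_column %in% names(df))
    stopf("label column '%s' not found in table", label_column)
  if (nrow(df) < 2L) stopf("need at least 2 samples, got %d", nrow(df))
  labels <- as.character(df[[label_column]])
  labels[trimws(tolower(labels)) %in% MISSING_MARKERS] <- NA_character_
  if (anyNA(labels)) stopf("label column '%s' has missing values", label_column)
  lev <- unique(labels)
  if (length(lev) != 2L)
    stopf("label column '%s' must have exactly 2 classes, found %d",
          label_column, length(lev))
  keep <- which(names(df) != label_column)  # by position: names may repeat
  if (length(keep) < 1L) stopf("no feature columns besides the label")
  feats <- as.data.frame(lapply(df[keep], parse_cell_column),
                         check.names = FALSE, optional = TRUE)
  names(feats) <- names(df)[keep]
  ids <- sample_ids %||% rownames(df) %||% as.character(seq_len(nrow(df)))
  new_raw_table(feats, labels, as.character(ids), label_column)
}

#' Load a CSV/TSV sample-by-feature table
#'
#' The delimiter is taken from the extension (`.tsv`/`.txt` means tab,
#' `.csv` comma) or sniffed from the header line. Samples are rows; the
#' header names the features.
#'
#' @inheritParams as_raw_table
#' @param path Path to the delimited file.
#' @return An object of class `eb_raw`.
#' @export
load_table <- function(path, label_column) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  sep <- if (ext %in% c("tsv", "txt")) "\t"
         else if (ext == "csv") ","
         else {
           hdr <- readLines(path, n = 1L)
           if (lengths(regmatches(hdr, gregexpr("\t", hdr))) >=
               lengths(regmatches(hdr, gregexpr(",", hdr)))) "\t" else ","
         }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", na.strings = NULL)
  as_raw_table(df, label_column)
}

#' Encode nominal feature columns as integers
#'
#' Every non-numeric column is replaced by integer codes assigned in
#' sorted lexical order of its distinct values (first value gets 0). The
#' mapping is recorded in `meta$encodings` for reporting.
#'
#' @param raw An `eb_raw` table.
#' @return The table with all feature columns numeric.
#' @export
encode_nominal <- function(raw) {
  stopifnot(inherits(raw, "eb_raw"))
  enc <- raw$meta$encodings %||% list()
  for (j in seq_along(raw$features)) {
    col <- raw$features[[j]]
    if (is.character(col)) {
      lev <- sort(unique(col[!is.na(col)]))
      raw$features[[j]] <- as.numeric(match(col, lev) - 1L)
      enc[[names(raw$features)[j]]] <- lev
    }
  }
  raw$meta$encodings <- enc
  raw
}

#' Impute missing feature values
#'
#' Default strategy is the class-conditional median: a missing cell is
#' filled with the median of its own class's observed values when both
#' classes have at least one observation for that feature, otherwise
#' with the global median. `"mean"` substitutes the mean in the same
#' scheme; `"knn"` fills with the mean of the `k` nearest samples
#' (Euclidean distance over jointly observed features).
#'
#' @param raw An `eb_raw` table with numeric features (see
#'   [encode_nominal()]).
#' @param strategy One of `"median"`, `"mean"`, `"knn"`.
#' @param k Number of neighbours for `"knn"`.
#' @return The table with no missing feature values.
#' @export
impute_missing <- function(raw, strategy = c("median", "mean", "knn"), k = 5L) {
  stopifnot(inherits(raw, "eb_raw"))
  strategy <- match.arg(strategy)
  X <- as.matrix(as.data.frame(raw$features, check.names = FALSE))
  storage.mode(X) <- "double"
  fully_missing <- colSums(!is.na(X)) == 0L
  if (any(fully_missing))
    stopf("fully-missing feature column(s): %s",
          paste(names(raw$features)[fully_missing], collapse = ", "))
  n_imputed <- sum(is.na(X))
  if (n_imputed > 0L) {
    if (strategy == "knn") {
      X <- impute_knn(X, k)
    } else {
      fun <- if (strategy == "median") stats::median else mean
      cls <- raw$labels
      lev <- unique(cls)
      for (j in which(colSums(is.na(X)) > 0L)) {
        x <- X[, j]
        obs_per_class <- vapply(lev, function(l) sum(!is.na(x[cls == l])), 0L)
        global <- fun(x[!is.na(x)])
        if (all(obs_per_class >= 1L)) {
          for (l in lev) {
            sel <- cls == l & is.na(x)
            if (any(sel)) x[sel] <- fun(x[cls == l & !is.na(x)])
          }
        } else {
          x[is.na(x)] <- global
        }
        X[, j] <- x
      }
    }
  }
  for (j in seq_along(raw$features)) raw$features[[j]] <- X[, j]
  raw$meta$imputation <- list(strategy = strategy, n_imputed = n_imputed)
  raw
}

impute_knn <- function(X, k) {
  n <- nrow(X)
  filled <- X
  for (i in which(rowSums(is.na(X)) > 0L)) {
    shared <- !is.na(X[i, ])
    d <- vapply(seq_len(n), function(m) {
      both <- shared & !is.na(X[m, ])
      if (!any(both) || m == i) return(Inf)
      sqrt(mean((X[i, both] - X[m, both])^2))
    }, 0)
    nb <- order(d)[seq_len(min(k, sum(is.finite(d))))]
    for (j in which(is.na(X[i, ]))) {
      v <- X[nb, j]
      filled[i, j] <- if (all(is.na(v))) mean(X[, j], na.rm = TRUE)
                      else mean(v, na.rm = TRUE)
    }
  }
  filled
}

#' Normalize features
#'
#' `"minmax"` (the default) maps each feature onto \[0, 1\]; constant
#' features map to 0. `"zscore"` centres and scales. Parameters are
#' learned on the full matrix once, before the evolutionary run, and
#' stored in `meta$normalization` for reuse on new data.
#'
#' @param raw An imputed `eb_raw` table.
#' @param method One of `"minmax"`, `"zscore"`, `"none"`.
#' @return The normalized table.
#' @export
normalize_features <- function(raw, method = c("minmax", "zscore", "none")) {
  stopifnot(inherits(raw, "eb_raw"))
  method <- match.arg(method)
  if (method == "none") {
    raw$meta$normalization <- list(method = "none")
    return(raw)
  }
  params <- vector("list", length(raw$features))
  for (j in seq_along(raw$features)) {
    x <- raw$features[[j]]
    if (method == "minmax") {
      lo <- min(x); hi <- max(x); rg <- hi - lo
      raw$features[[j]] <- if (rg > 0) (x - lo) / rg else rep(0, length(x))
      params[[j]] <- c(min = lo, range = rg)
    } else {
      mu <- mean(x); sdv <- stats::sd(x)
      raw$features[[j]] <- if (sdv > 0) (x - mu) / sdv else rep(0, length(x))
      params[[j]] <- c(mean = mu, sd = sdv)
    }
  }
  names(params) <- names(raw$features)
  raw$meta$normalization <- list(method = method, params = params)
  raw
}

#' Merge duplicate-named features and finalize the dataset
#'
#' Columns sharing an identical feature name are replaced by one column
#' equal to their element-wise mean. Labels are mapped to \{0, 1\}; by
#' default the minority class becomes the positive class (ties broken by
#' lexicographically last label).
#'
#' @param raw A fully preprocessed `eb_raw` table.
#' @param positive_label Optional label value to map to 1.
#' @return An object of class `eb_dataset` with fields `X` (n-by-p
#'   numeric matrix), `y` (0/1 vector), `feature_names`, `sample_ids`,
#'   `positive_label`, and the preprocessing `meta`.
#' @export
merge_duplicate_features <- function(raw, positive_label = NULL) {
  stopifnot(inherits(raw, "eb_raw"))
  X <- as.matrix(as.data.frame(raw$features, check.names = FALSE))
  storage.mode(X) <- "double"
  colnames(X) <- names(raw$features)
  nm <- colnames(X)
  merged_groups <- list()
  if (anyDuplicated(nm)) {
    uniq <- unique(nm)
    Xm <- matrix(0, nrow(X), length(uniq), dimnames = list(NULL, uniq))
    for (u in uniq) {
      idx <- which(nm == u)
      Xm[, u] <- if (length(idx) == 1L) X[, idx]
                 else rowMeans(X[, idx, drop = FALSE])
      if (length(idx) > 1L) merged_groups[[u]] <- idx
    }
    X <- Xm
  }
  lev <- unique(raw$labels)
  if (is.null(positive_label)) {
    cnt <- table(raw$labels)
    m <- min(cnt)
    cand <- sort(names(cnt)[cnt == m])
    positive_label <- cand[length(cand)]
  }
  if (!positive_label %in% lev)
    stopf("positive_label '%s' is not a label value", positive_label)
  y <- as.integer(raw$labels == positive_label)
  if (length(unique(y)) != 2L) stopf("both classes must be present")
  meta <- raw$meta
  meta$merged_duplicates <- merged_groups
  rownames(X) <- raw$sample_ids
  structure(
    list(X = X, y = y, feature_names = colnames(X),
         sample_ids = raw$sample_ids, positive_label = positive_label,
         meta = meta),
    class = "eb_dataset"
  )
}

#' Run the full preprocessing chain
#'
#' Nominal encoding, imputation, normalization and duplicate merging, in
#' that order. The chain is idempotent: reapplying it to its own output
#' leaves the matrix unchanged.
#'
#' @param raw An `eb_raw` table (see [load_table()], [as_raw_table()]).
#' @param impute Imputation strategy, see [impute_missing()].
#' @param normalize Normalization method, see [normalize_features()].
#' @param positive_label Optional label to map to 1.
#' @return An `eb_dataset`.
#' @export
preprocess_table <- function(raw, impute = "median", normalize = "minmax",
                             positive_label = NULL) {
  raw <- encode_nominal(raw)
  raw <- impute_missing(raw, impute)
  raw <- normalize_features(raw, normalize)
  merge_duplicate_features(raw, positive_label)
}

#' Preprocessing report
#'
#' @param dataset An `eb_dataset`.
#' @return A list with the nominal encodings, imputation counts and
#'   merged-duplicate groups, suitable for JSON export.
#' @export
preprocessing_report <- function(dataset) {
  stopifnot(inherits(dataset, "eb_dataset"))
  list(
    n_samples = nrow(dataset$X),
    n_features = ncol(dataset$X),
    positive_label = dataset$positive_label,
    class_counts = as.list(table(dataset$y)),
    encodings = dataset$meta$encodings %||% list(),
    imputation = dataset$meta$imputation %||% list(),
    normalization = list(method = dataset$meta$normalization$method %||% "none"),
    merged_duplicates = dataset$meta$merged_duplicates %||% list()
  )
}

#' @export
print.eb_dataset <- function(x, ...) {
  cat(sprintf("<eb_dataset> %d samples x %d features; positives (%s): %d, negatives: %d\n",
              nrow(x$X), ncol(x$X), x$positive_label, sum(x$y == 1L),
              sum(x$y == 0L)))
  invisible(x)
}
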