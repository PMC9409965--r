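#' Construct a two-class omics measurement table
#'
#' An `omics_table` is the container every stage of the package consumes: an
#' N x F numeric matrix of measurements (rows are samples, columns are
#' features such as metabolite concentrations) together with sample
#' identifiers, feature names, and a binary class label per sample
#' (case = 1, control = 0).
#'
#' @param values Numeric N x F matrix (or coercible data frame) of
#'   measurements. No missing values are allowed.
#' @param labels Vector of length N with exactly two distinct values. Coerced
#'   to 0/1: the lexicographically smaller original label maps to 0. The
#'   mapping is recorded in the `label_map` attribute.
#' @param sample_ids Optional character vector of N sample identifiers.
#' @param feature_names Optional character vector of F unique feature names.
#'
#' @return An object of class `omics_table`: a list with elements `values`,
#'   `labels` (integer 0/1), `sample_ids`, `feature_names`, `label_map`.
#' @export
#'
#' @examples
#' x <- matrix(rnorm(40), nrow = 10)
#' tab <- omics_table(x, labels = rep(c("ctrl", "case"), each = 5))
#' tab$label_map
omics_table <- function(values, labels, sample_ids = NULL, feature_names = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix or data frame", call. = FALSE)
  }
  n <- nrow(values)
  f <- ncol(values)
  if (n < 4L) stop("at least 4 samples are required", call. = FALSE)
  if (f < 1L) stop("at least 1 feature is required", call. = FALSE)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (length(labels) != n) {
    stop("`labels` must have one entry per row of `values`", call. = FALSE)
  }
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L) {
    stop(sprintf("label column must be binary; found %d distinct values (%s)",
                 length(lev), paste(utils::head(lev, 5L), collapse = ", ")),
         call. = FALSE)
  }
  lab01 <- as.integer(as.character(labels) == lev[2L])
  if (is.null(feature_names)) {
    feature_names <- colnames(values) %||% paste0("feature_", seq_len(f))
  }
  if (anyDuplicated(feature_names)) {
    stop("feature names must be unique", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values) %||% paste0("sample_", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  feature_names <- as.character(feature_names)
  dimnames(values) <- list(sample_ids, feature_names)
  structure(
    list(values = values, labels = lab01, sample_ids = sample_ids,
         feature_names = feature_names,
         label_map = stats::setNames(0:1, lev)),
    class = "omics_table"
  )
}

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf("omics_table: %d samples x %d features (%d cases / %d controls)\n",
              nrow(x$values), ncol(x$values), sum(x$labels == 1L),
              sum(x$labels == 0L)))
  cat("label coding:",
      paste(sprintf("%s=%d", names(x$label_map), x$label_map), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.omics_table <- function(x) dim(x$values)

# Restrict a table to a subset of features (order as given).
subset_features <- function(table, features) {
  stopifnot(inherits(table, "omics_table"))
  missing <- setdiff(features, table$feature_names)
  if (length(missing)) {
    stop("unknown feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- table
  out$values <- table$values[, features, drop = FALSE]
  out$feature_names <- features
  out
}

# Restrict a table to a subset of samples.
subset_samples <- function(table, idx) {
  out <- table
  out$values <- table$values[idx, , drop = FALSE]
  out$labels <- table$labels[idx]
  out$sample_ids <- table$sample_ids[idx]
  out
}

#' Read a samples-by-features table with a label column
#'
#' Reads a CSV or TSV file with a header row, one sample per row, and one
#' designated label column, and validates it into an [omics_table()]. The
#' delimiter is inferred from the file extension (`.tsv`/`.txt` = tab,
#' otherwise comma) and can be overridden.
#'
#' @param path Path to the file.
#' @param label_column Name of the label column.
#' @param sep Field delimiter; `NULL` (default) infers from the extension.
#'
#' @return An [omics_table()]. Row and column order are preserved.
#' @export
read_omics_table <- function(path, label_column, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!label_column %in% names(df)) {
    stop(sprintf("label column '%s' not found in %s", label_column, path),
         call. = FALSE)
  }
  labels <- df[[label_column]]
  vals <- df[, setdiff(names(df), label_column), drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !anyNA(v)) {
        bad <- which(is.na(vn))[1L]
        stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                     v[bad], names(vals)[j], bad), call. = FALSE)
      }
      vals[[j]] <- vn
    }
    if (anyNA(vals[[j]])) {
      bad <- which(is.na(vals[[j]]))[1L]
      stop(sprintf("missing value in column '%s', row %d", names(vals)[j], bad),
           call. = FALSE)
    }
  }
  rn <- rownames(df)
  if (identical(rn, as.character(seq_len(nrow(df))))) rn <- NULL
  omics_table(as.matrix(vals), labels = labels, sample_ids = rn)
}

#' Write an omics table to CSV/TSV
#'
#' Inverse of [read_omics_table()]: writes the measurement columns plus the
#' label column (original label values restored from the recorded coding).
#'
#' @param table An [omics_table()].
#' @param path Output path; extension selects the delimiter as in
#'   [read_omics_table()].
#' @param label_column Name for the label column (default `"label"`).
#' @return Invisibly, `path`.
#' @export
write_omics_table <- function(table, path, label_column = "label") {
  stopifnot(inherits(table, "omics_table"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  lev <- names(table$label_map)
  df <- as.data.frame(table$values, check.names = FALSE)
  df[[label_column]] <- lev[table$labels + 1L]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standardize features to zero mean and unit variance
#'
#' Centers and scales each feature column. When `params` is supplied (e.g.
#' fitted on a training partition) it is applied unchanged, which is how test
#' data must be standardized to avoid information leakage.
#'
#' @param table An [omics_table()].
#' @param params Optional `standardization_params` (means and standard
#'   deviations per feature) to apply; if `NULL` they are computed from
#'   `table` itself.
#'
#' @return A list with `table` (the standardized [omics_table()]) and
#'   `params` (class `standardization_params`, fields `means` and `stds`).
#' @export
standardize <- function(table, params = NULL) {
  stopifnot(inherits(table, "omics_table"))
  x <- table$values
  if (is.null(params)) {
    means <- colMeans(x)
    stds <- col_sds(x)
    if (any(stds == 0)) {
      bad <- table$feature_names[stds == 0]
      stop("zero-variance feature(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    params <- structure(list(means = means, stds = stds),
                        class = "standardization_params")
  } else {
    stopifnot(inherits(params, "standardization_params"))
    if (length(params$means) != ncol(x)) {
      stop("standardization params do not match the number of features",
           call. = FALSE)
    }
  }
  out <- table
  out$values <- sweep(sweep(x, 2L, params$means, "-"), 2L, params$stds, "/")
  list(table = out, params = params)
}

#' Split samples into training and testing partitions
#'
#' Draws a seeded random train/test split. In stratified mode (the default)
#' the split is drawn within each class so class proportions are preserved
#' to within one sample per class; this avoids degenerate one-class test
#' partitions in small Monte Carlo studies.
#'
#' @param table An [omics_table()].
#' @param ratio Fraction of samples assigned to the training set (default 0.7).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param stratified Stratify by class label (default `TRUE`).
#'
#' @return An object of class `train_test_split` with integer index vectors
#'   `train` and `test` (disjoint, jointly covering all samples), plus the
#'   `ratio` and `seed` used.
#' @export
make_split <- function(table, ratio = 0.7, seed = 1L, stratified = TRUE) {
  stopifnot(inherits(table, "omics_table"))
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must be in (0, 1)", call. = FALSE)
  n <- nrow(table$values)
  train <- with_seed(seed, {
    if (stratified) {
      # largest-remainder allocation: per-class counts within one of the
      # class proportion while the total train size is exactly round(ratio*N)
      target <- max(1L, min(n - 1L, round(ratio * n)))
      sizes <- vapply(c(0L, 1L), function(cl) sum(table$labels == cl),
                      integer(1))
      base <- pmin(pmax(floor(ratio * sizes), 1L), sizes - 1L)
      short <- target - sum(base)
      if (short > 0L) {
        ord <- order(ratio * sizes - floor(ratio * sizes), decreasing = TRUE)
        for (i in seq_len(short)) {
          cl <- ord[(i - 1L) %% 2L + 1L]
          if (base[cl] < sizes[cl] - 1L) base[cl] <- base[cl] + 1L
        }
      }
      idx <- integer(0)
      for (cl in c(0L, 1L)) {
        members <- which(table$labels == cl)
        idx <- c(idx, sample(members, base[cl + 1L]))
      }
      sort(idx)
    } else {
      n_tr <- round(ratio * n)
      n_tr <- max(1L, min(n - 1L, n_tr))
      sort(sample.int(n, n_tr))
    }
  })
  test <- setdiff(seq_len(n), train)
  if (!stratified) {
    for (part in list(train = train, test = test)) {
      if (length(unique(table$labels[part])) < 2L) {
        warning("a partition contains a single class", call. = FALSE)
        break
      }
    }
  }
  structure(list(train = train, test = sort(test), ratio = ratio, seed = seed),
            class = "train_test_split")
}
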