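#' Describe a classifier to be evaluated
#'
#' A `classifier_spec` names one of the six supported algorithms, an optional
#' ordered feature subset (the biomarker panel), and hyperparameter
#' overrides. The defaults follow common practice for small tabular omics
#' panels: LDA as the Fisher discriminant; a linear-kernel soft-margin SVM
#' (cost 1) so per-feature coefficients exist; a random forest with 16 trees
#' and Gini splitting; one-component PLS-DA with a 0.5 decision threshold on
#' the continuous output; ridge-penalized logistic regression; and a
#' fully-connected 32-16 two-hidden-layer perceptron with ReLU activations
#' and a logistic output.
#'
#' @param algorithm One of `"LDA"`, `"SVM"`, `"RF"`, `"PLSDA"`, `"LOG"`,
#'   `"MLP"`.
#' @param features Optional ordered character vector of input feature names;
#'   `NULL` means all columns of the training matrix.
#' @param hyperparameters Named list of overrides; unknown names are an error.
#'
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(algorithm = c("LDA", "SVM", "RF", "PLSDA", "LOG", "MLP"),
                            features = NULL, hyperparameters = list()) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    LDA = list(),
    SVM = list(cost = 1),
    RF = list(ntree = 16L),
    PLSDA = list(ncomp = 1L, threshold = 0.5),
    LOG = list(lambda = NULL, alpha = 0),  # lambda NULL -> 1/n at fit time
    MLP = list(hidden = c(32L, 16L), maxit = 1000L, learn_rate = 0.01)
  )
  unknown <- setdiff(names(hyperparameters), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown hyperparameter(s) for %s: %s", algorithm,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(algorithm = algorithm, features = features,
                 hyperparameters = hp),
            class = "classifier_spec")
}

# Resolve the design matrix for a spec: restrict to the declared subset.
resolve_features <- function(spec, x) {
  if (is.null(spec$features)) return(x)
  missing <- setdiff(spec$features, colnames(x))
  if (length(missing)) {
    stop("feature(s) not in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x[, spec$features, drop = FALSE]
}

#' Fit a classifier under a spec
#'
#' Fits the algorithm named by `spec` on a (standardized) training matrix and
#' 0/1 labels. Stochastic algorithms (RF, MLP, the LOG solver) are seeded so
#' identical inputs reproduce identical fits.
#'
#' @param spec A [classifier_spec()].
#' @param x_train Numeric matrix with named columns, already standardized.
#' @param y_train Integer 0/1 labels, both classes present.
#' @param seed Integer seed.
#'
#' @return An object of class `rc_fit` holding the fitted model, the
#'   extracted [extract_params()] vector, and fitting metadata. Use
#'   [predict()] to classify new rows.
#' @export
fit_classifier <- function(spec, x_train, y_train, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- resolve_features(spec, as.matrix(x_train))
  y <- as.integer(y_train)
  if (length(unique(y)) < 2L) stop("training labels contain a single class",
                                   call. = FALSE)
  if (nrow(x) != length(y)) stop("x_train/y_train size mismatch", call. = FALSE)
  hp <- spec$hyperparameters
  model <- with_seed(seed, switch(spec$algorithm,
    LDA = MASS::lda(x, grouping = factor(y, levels = 0:1)),
    SVM = e1071::svm(x, factor(y, levels = 0:1), kernel = "linear",
                     cost = hp$cost, scale = FALSE),
    RF = randomForest::randomForest(x, factor(y, levels = 0:1),
                                    ntree = hp$ntree),
    PLSDA = pls1_fit(x, y, threshold = hp$threshold),
    LOG = fit_ridge_logistic(x, y, lambda = hp$lambda, alpha = hp$alpha),
    MLP = mlp_fit(x, y, hidden = hp$hidden, maxit = hp$maxit,
                  learn_rate = hp$learn_rate)
  ))
  fit <- structure(list(spec = spec, model = model, seed = seed,
                        feature_names = colnames(x)),
                   class = "rc_fit")
  fit$params <- extract_params(fit)
  fit
}

fit_ridge_logistic <- function(x, y, lambda = NULL, alpha = 0) {
  if (is.null(lambda)) lambda <- 1 / nrow(x)
  if (ncol(x) >= 2L) {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                          lambda = lambda, standardize = FALSE)
    list(engine = "glmnet", fit = fit, lambda = lambda)
  } else {
    # glmnet requires >= 2 predictors; plain IRLS is fine univariately
    df <- data.frame(y = y, x1 = x[, 1L])
    fit <- suppressWarnings(stats::glm(y ~ x1, data = df, family = stats::binomial()))
    list(engine = "glm", fit = fit, lambda = 0)
  }
}

#' Predict class labels from a fitted classifier
#'
#' @param object An `rc_fit` from [fit_classifier()].
#' @param newdata Numeric matrix containing the fit's feature columns,
#'   standardized with the training partition's parameters.
#' @param ... Unused.
#'
#' @return Integer vector of 0/1 labels, one per row of `newdata` (empty
#'   input gives an empty vector). For PLS-DA a continuous score of exactly
#'   the threshold is assigned to class 1.
#' @export
predict.rc_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (nrow(x) == 0L) return(integer(0))
  missing <- setdiff(object$feature_names, colnames(x))
  if (length(missing)) {
    stop("feature(s) not in newdata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- x[, object$feature_names, drop = FALSE]
  m <- object$model
  out <- switch(object$spec$algorithm,
    LDA = as.integer(as.character(stats::predict(m, x)$class)),
    SVM = as.integer(as.character(stats::predict(m, x))),
    RF = as.integer(as.character(stats::predict(m, x))),
    PLSDA = pls1_predict(m, x),
    LOG = if (m$engine == "glmnet") {
      as.integer(stats::predict(m$fit, newx = x, s = m$lambda,
                                type = "class"))
    } else {
      as.integer(stats::predict(m$fit,
                                newdata = data.frame(x1 = x[, 1L]),
                                type = "response") >= 0.5)
    },
    MLP = mlp_predict(m, x)
  )
  unname(out)
}

#' Extract feature-aligned parameters from a fit
#'
#' Returns the per-feature parameter vector that the Monte Carlo studies
#' track across corruptions: signed coefficients for the linear models
#' (LDA discriminant weights, linear-SVM weights, the one-component PLS-DA
#' regression coefficients, logistic weights) and normalized mean decrease in
#' Gini impurity for the random forest. The MLP has no per-feature weights,
#' so its kind is `"none"` and it is excluded from parameter tracking.
#'
#' @param fit An `rc_fit`.
#'
#' @return A `param_vector`: list with `kind` (`"coefficient"`,
#'   `"importance"`, or `"none"`) and `entries`, a named numeric vector with
#'   one entry per input feature (empty for kind `"none"`). Importances are
#'   non-negative and sum to 1.
#' @export
extract_params <- function(fit) {
  stopifnot(inherits(fit, "rc_fit"))
  m <- fit$model
  feats <- fit$feature_names
  out <- switch(fit$spec$algorithm,
    LDA = list(kind = "coefficient",
               entries = stats::setNames(m$scaling[, 1L], feats)),
    SVM = {
      w <- drop(t(m$coefs) %*% m$SV)
      list(kind = "coefficient", entries = stats::setNames(w[feats], feats))
    },
    RF = {
      imp <- m$importance[, "MeanDecreaseGini"]
      s <- sum(imp)
      if (s <= 0) imp[] <- 1 / length(imp) else imp <- imp / s
      list(kind = "importance", entries = stats::setNames(imp[feats], feats))
    },
    PLSDA = list(kind = "coefficient",
                 entries = stats::setNames(m$beta, feats)),
    LOG = {
      w <- if (m$engine == "glmnet") {
        drop(as.matrix(stats::coef(m$fit, s = m$lambda)))[-1L]
      } else {
        stats::coef(m$fit)[-1L]
      }
      list(kind = "coefficient", entries = stats::setNames(unname(w), feats))
    },
    MLP = list(kind = "none", entries = stats::setNames(numeric(0), character(0)))
  )
  structure(out, class = "param_vector")
}

#' Leave-one-out cross-validation accuracy
#'
#' Fits N models, each with one sample held out, and reports the fraction of
#' held-out samples classified correctly. A fold whose training partition
#' loses a class cannot be fit; its prediction is counted as incorrect and a
#' warning is raised.
#'
#' @param spec A [classifier_spec()].
#' @param x Standardized numeric matrix.
#' @param y Integer 0/1 labels.
#' @param seed Integer seed (per-fold streams are derived from it).
#'
#' @return Accuracy as an exact fraction correct / N.
#' @export
loocv_accuracy <- function(spec, x, y, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) stop("LOOCV requires at least 4 samples", call. = FALSE)
  correct <- 0L
  degenerate <- 0L
  for (i in seq_len(n)) {
    y_tr <- y[-i]
    if (length(unique(y_tr)) < 2L) {
      degenerate <- degenerate + 1L
      next
    }
    fit <- fit_classifier(spec, x[-i, , drop = FALSE], y_tr,
                          seed = derive_seed(seed, i))
    pred <- predict(fit, x[i, , drop = FALSE])
    if (pred == y[i]) correct <- correct + 1L
  }
  if (degenerate > 0L) {
    warning(sprintf("%d LOOCV fold(s) lost a class; counted as incorrect",
                    degenerate), call. = FALSE)
  }
  correct / n
}

#' Wrapper feature selection by exhaustive subset search
#'
#' Evaluates every size-`k` feature subset by the LOOCV accuracy of a
#' classifier trained on the fixed split's training partition, and returns
#' the best subset. Ties are broken in favor of the earlier subset in
#' lexicographic feature order.
#'
#' @param table An [omics_table()] (raw scale; standardization is fitted on
#'   the training partition).
#' @param algorithm Algorithm name as in [classifier_spec()].
#' @param k Subset size (the study design uses 5-feature panels).
#' @param split A [make_split()] result fixing the training partition.
#' @param cap Maximum number of subsets to enumerate (default 200000).
#' @param hyperparameters Passed to [classifier_spec()].
#' @param seed Integer seed for the per-subset fits.
#'
#' @return A list with `spec` (the winning [classifier_spec()]), `accuracy`
#'   (its LOOCV accuracy), and `n_evaluated`.
#' @export
wrapper_select_features <- function(table, algorithm, k, split,
                                    cap = 200000L, hyperparameters = list(),
                                    seed = 1L) {
  stopifnot(inherits(table, "omics_table"), inherits(split, "train_test_split"))
  feats <- table$feature_names
  f <- length(feats)
  if (k > f) stop("`k` exceeds the number of features", call. = FALSE)
  n_comb <- choose(f, k)
  if (n_comb > cap) {
    stop(sprintf(paste0("%d subsets exceed the enumeration cap (%d); use ",
                        "prevalence_rank_features() or a smaller k"),
                 n_comb, cap), call. = FALSE)
  }
  train <- subset_samples(table, split$train)
  std <- standardize(train)
  x_tr <- std$table$values
  y_tr <- train$labels
  combos <- utils::combn(f, k)
  best_acc <- -Inf
  best_idx <- NULL
  for (ci in seq_len(ncol(combos))) {
    subset <- feats[combos[, ci]]
    spec <- classifier_spec(algorithm, features = subset,
                            hyperparameters = hyperparameters)
    acc <- loocv_accuracy(spec, x_tr[, subset, drop = FALSE], y_tr,
                          seed = derive_seed(seed, ci))
    if (acc > best_acc) {
      best_acc <- acc
      best_idx <- ci
    }
  }
  list(spec = classifier_spec(algorithm, features = feats[combos[, best_idx]],
                              hyperparameters = hyperparameters),
       accuracy = best_acc, n_evaluated = ncol(combos))
}

#' Rank features by prevalence among winning subsets
#'
#' Validation companion to [wrapper_select_features()]: over `n_splits`
#' seeded 70/30 splits, the size-`k` subset with the best test-partition
#' accuracy is recorded, and each feature's prevalence is the fraction of
#' winning subsets containing it. The recommended panel prefers subsets all
#' of whose members lie in the top third of the prevalence ranking, even at
#' lower accuracy, over panels with less prevalent members.
#'
#' @inheritParams wrapper_select_features
#' @param n_splits Number of random splits (the study design uses 1000).
#' @param ratio Training fraction per split (default 0.7).
#' @param seed Master seed.
#'
#' @return A list with `prevalence` (named vector over all features, sorted
#'   decreasing), `spec` (recommended [classifier_spec()]), and `winners`
#'   (list of winning subsets per split).
#' @export
prevalence_rank_features <- function(table, algorithm, k, n_splits = 1000L,
                                     ratio = 0.7, cap = 200000L,
                                     hyperparameters = list(), seed = 1L) {
  stopifnot(inherits(table, "omics_table"))
  if (n_splits < 2L) stop("`n_splits` must be at least 2", call. = FALSE)
  feats <- table$feature_names
  f <- length(feats)
  n_comb <- choose(f, k)
  if (n_comb > cap) {
    stop(sprintf("%d subsets exceed the enumeration cap (%d)", n_comb, cap),
         call. = FALSE)
  }
  combos <- utils::combn(f, k)
  winners <- vector("list", n_splits)
  winner_acc <- numeric(n_splits)
  for (si in seq_len(n_splits)) {
    split <- make_split(table, ratio = ratio, seed = derive_seed(seed, si))
    train <- subset_samples(table, split$train)
    test <- subset_samples(table, split$test)
    std <- standardize(train)
    x_tr <- std$table$values
    x_te <- standardize(test, std$params)$table$values
    accs <- vapply(seq_len(ncol(combos)), function(ci) {
      subset <- feats[combos[, ci]]
      spec <- classifier_spec(algorithm, features = subset,
                              hyperparameters = hyperparameters)
      fit <- fit_classifier(spec, x_tr[, subset, drop = FALSE], train$labels,
                            seed = derive_seed(seed, si, ci))
      mean(predict(fit, x_te[, subset, drop = FALSE]) == test$labels)
    }, numeric(1))
    # small test partitions quantize accuracy, so exact ties among winning
    # subsets are common; a seeded random pick among the tied maxima avoids
    # biasing prevalence toward early-enumerated features
    tied <- which(accs == max(accs))
    best_ci <- if (length(tied) == 1L) tied else {
      with_seed(derive_seed(seed, si, 0L), sample(tied, 1L))
    }
    winners[[si]] <- feats[combos[, best_ci]]
    winner_acc[si] <- accs[best_ci]
  }
  hits <- table(factor(unlist(winners), levels = feats))
  prevalence <- sort(stats::setNames(as.numeric(hits) / n_splits, feats),
                     decreasing = TRUE)
  top_third <- names(prevalence)[seq_len(ceiling(f / 3))]
  all_in_top <- vapply(winners, function(w) all(w %in% top_third), logical(1))
  pick <- if (any(all_in_top)) {
    cand <- which(all_in_top)
    cand[which.max(winner_acc[cand])]
  } else {
    keys <- vapply(winners, function(w) paste(sort(w), collapse = "|"),
                   character(1))
    which(keys == names(which.max(table(keys))))[1L]
  }
  list(prevalence = prevalence,
       spec = classifier_spec(algorithm, features = winners[[pick]],
                              hyperparameters = hyperparameters),
       winners = winners)
}

#' Grid search over hyperparameters by training-partition LOOCV
#'
#' Exhaustively evaluates every combination in `grid` by LOOCV accuracy on
#' the split's training partition and returns the best combination; ties are
#' broken in favor of the earlier combination in grid order.
#'
#' @inheritParams wrapper_select_features
#' @param grid Named list mapping hyperparameter names to candidate value
#'   vectors.
#'
#' @return A list with `hyperparameters` (the winning named list) and
#'   `accuracy` (its LOOCV accuracy).
#' @export
grid_search_hyperparams <- function(table, algorithm, grid, split, seed = 1L) {
  stopifnot(inherits(table, "omics_table"), length(grid) >= 1L)
  train <- subset_samples(table, split$train)
  std <- standardize(train)
  x_tr <- std$table$values
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  best_acc <- -Inf
  best_row <- 1L
  for (ri in seq_len(nrow(combos))) {
    hp <- as.list(combos[ri, , drop = FALSE])
    names(hp) <- names(combos)
    spec <- classifier_spec(algorithm, hyperparameters = hp)
    acc <- loocv_accuracy(spec, x_tr, train$labels, seed = derive_seed(seed, ri))
    if (acc > best_acc) {
      best_acc <- acc
      best_row <- ri
    }
  }
  hp <- as.list(combos[best_row, , drop = FALSE])
  names(hp) <- names(combos)
  list(hyperparameters = hp, accuracy = best_acc)
}
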