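#' Noise-severity sweep
#'
#' The core Monte Carlo protocol: for each noise level and repetition the
#' raw table is corrupted, standardization is then fitted on the corrupted
#' training partition (corruption precedes standardization) and applied to
#' the corrupted test partition, the classifier is fitted, and the
#' test-partition accuracy, optionally the LOOCV accuracy of the training
#' partition, and the feature-aligned parameter vector are recorded. The same
#' fixed split is reused for every repetition and level so that only the
#' sampled noise varies. Means and variances are aggregated per level.
#'
#' @param table An [omics_table()] on the raw measurement scale.
#' @param spec A [classifier_spec()].
#' @param kind `"replacement"` or `"gaussian"`.
#' @param levels Ordered noise levels (default `seq(0, 1, 0.1)`).
#' @param reps Corruptions per level (the study design uses 1000; 100 is a
#'   practical desk-scale default).
#' @param split A [make_split()] result; fixed across all repetitions.
#' @param seed Master seed. Repetition r at level index l uses a stream
#'   derived from `(seed, l, r)`, so partial or parallel runs reproduce the
#'   serial result.
#' @param track_loocv Record LOOCV training accuracy per repetition
#'   (default `FALSE`; LOOCV multiplies the fit count by the training-set
#'   size).
#' @param clip_negative Passed to [noise_spec()]; `NULL` keeps each engine's
#'   default.
#'
#' @return A `sweep_result`: list with `summary` (data frame, one row per
#'   level: `level`, `mean_test_acc`, `var_test_acc`, `mean_loocv_acc`,
#'   `var_loocv_acc`), `param_mean` / `param_var` (levels x features
#'   matrices, `NULL` for parameter-free classifiers), `accuracies` (reps x
#'   levels matrix of raw test accuracies), and provenance fields.
#' @export
severity_sweep <- function(table, spec, kind = c("replacement", "gaussian"),
                           levels = seq(0, 1, 0.1), reps = 100L, split,
                           seed = 1L, track_loocv = FALSE,
                           clip_negative = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(table, "omics_table"), inherits(spec, "classifier_spec"),
            inherits(split, "train_test_split"))
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("`levels` must be strictly increasing", call. = FALSE)
  }
  if (reps < 2L) stop("`reps` must be at least 2", call. = FALSE)
  n_lev <- length(levels)
  acc <- matrix(NA_real_, reps, n_lev)
  loocv <- if (track_loocv) matrix(NA_real_, reps, n_lev) else NULL
  param_store <- NULL
  feats <- NULL
  for (li in seq_len(n_lev)) {
    failures <- 0L
    for (r in seq_len(reps)) {
      rep_seed <- derive_seed(seed, li, r)
      res <- tryCatch(
        run_one_rep(table, spec, split,
                    noise = noise_spec(kind, levels[li],
                                       clip_negative = clip_negative,
                                       seed = rep_seed),
                    seed = rep_seed, track_loocv = track_loocv),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures <- failures + 1L
        next
      }
      acc[r, li] <- res$test_acc
      if (track_loocv) loocv[r, li] <- res$loocv_acc
      if (res$params$kind != "none") {
        if (is.null(param_store)) {
          feats <- names(res$params$entries)
          param_store <- array(NA_real_, dim = c(reps, n_lev, length(feats)),
                               dimnames = list(NULL, NULL, feats))
        }
        param_store[r, li, ] <- res$params$entries
      }
    }
    if (failures > 0.05 * reps) {
      stop(sprintf("more than 5%% of repetitions failed at level %g (%d/%d)",
                   levels[li], failures, reps), call. = FALSE)
    }
    if (failures > 0L) {
      message(sprintf("severity_sweep: %d failed repetition(s) at level %g excluded",
                      failures, levels[li]))
    }
  }
  summary <- data.frame(
    level = levels,
    mean_test_acc = colMeans(acc, na.rm = TRUE),
    var_test_acc = apply(acc, 2L, stats::var, na.rm = TRUE),
    mean_loocv_acc = if (track_loocv) colMeans(loocv, na.rm = TRUE) else NA_real_,
    var_loocv_acc = if (track_loocv) apply(loocv, 2L, stats::var, na.rm = TRUE) else NA_real_
  )
  param_mean <- param_var <- NULL
  if (!is.null(param_store)) {
    param_mean <- apply(param_store, c(2L, 3L), mean, na.rm = TRUE)
    param_var <- apply(param_store, c(2L, 3L), stats::var, na.rm = TRUE)
    dimnames(param_mean) <- dimnames(param_var) <- list(NULL, feats)
  }
  structure(list(kind = kind, levels = levels, reps = reps, spec = spec,
                 split = split, seed = seed, summary = summary,
                 param_mean = param_mean, param_var = param_var,
                 accuracies = acc),
            class = "sweep_result")
}

# One corruption-fit-score repetition shared by the sweep protocols.
run_one_rep <- function(table, spec, split, noise = NULL, seed = 1L,
                        track_loocv = FALSE) {
  work <- if (is.null(noise)) table else corrupt(table, noise)
  train <- subset_samples(work, split$train)
  test <- subset_samples(work, split$test)
  std <- standardize(train)
  x_tr <- std$table$values
  x_te <- standardize(test, std$params)$table$values
  fit <- fit_classifier(spec, x_tr, train$labels, seed = seed)
  x_fit <- resolve_features(spec, x_te)
  test_acc <- mean(predict(fit, x_fit) == test$labels)
  loocv_acc <- if (track_loocv) {
    loocv_accuracy(spec, resolve_features(spec, x_tr), train$labels,
                   seed = seed)
  } else {
    NA_real_
  }
  list(test_acc = test_acc, loocv_acc = loocv_acc, params = fit$params)
}

#' Monte Carlo train/test-split study
#'
#' Complements the noise sweeps: the uncorrupted table is split into 70/30
#' training/testing partitions many times, and the test accuracy, LOOCV
#' training accuracy, and parameter vector are recorded per split. A
#' classifier whose accuracy swings strongly with the split is unlikely to
#' generalize; the variance of the LOOCV accuracy is characteristically
#' lower than the test-partition variance, making varied splits the more
#' stringent stress test.
#'
#' @inheritParams severity_sweep
#' @param n_splits Number of random splits (study design: 1000).
#' @param ratio Training fraction (default 0.7).
#' @param stratified Stratify splits by class (default `TRUE`).
#' @param split_seeds Optional integer vector of per-split seeds (length
#'   `n_splits`); by default seeds are derived from `seed`.
#'
#' @return A `split_study_result`: list with `test_acc` and `loocv_acc`
#'   per-split vectors, their `mean_*` / `var_*` scalars, `param_mean` /
#'   `param_var` (named vectors across splits), and provenance fields.
#' @export
mc_split_study <- function(table, spec, n_splits = 100L, ratio = 0.7,
                           seed = 1L, stratified = TRUE, track_loocv = TRUE,
                           split_seeds = NULL) {
  stopifnot(inherits(table, "omics_table"), inherits(spec, "classifier_spec"))
  if (n_splits < 2L) stop("`n_splits` must be at least 2", call. = FALSE)
  if (is.null(split_seeds)) {
    split_seeds <- vapply(seq_len(n_splits), function(si) derive_seed(seed, si),
                          integer(1))
  }
  stopifnot(length(split_seeds) == n_splits)
  test_acc <- loocv_acc <- rep(NA_real_, n_splits)
  param_store <- NULL
  feats <- NULL
  failures <- 0L
  for (si in seq_len(n_splits)) {
    split <- make_split(table, ratio = ratio, seed = split_seeds[si],
                        stratified = stratified)
    res <- tryCatch(
      run_one_rep(table, spec, split, noise = NULL,
                  seed = derive_seed(split_seeds[si], 1L),
                  track_loocv = track_loocv),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- failures + 1L
      next
    }
    test_acc[si] <- res$test_acc
    loocv_acc[si] <- res$loocv_acc
    if (res$params$kind != "none") {
      if (is.null(param_store)) {
        feats <- names(res$params$entries)
        param_store <- matrix(NA_real_, n_splits, length(feats),
                              dimnames = list(NULL, feats))
      }
      param_store[si, ] <- res$params$entries
    }
  }
  if (failures > 0.05 * n_splits) {
    stop(sprintf("more than 5%% of splits failed (%d/%d)", failures, n_splits),
         call. = FALSE)
  }
  structure(list(n_splits = n_splits, ratio = ratio, seed = seed, spec = spec,
                 test_acc = test_acc, loocv_acc = loocv_acc,
                 mean_test_acc = mean(test_acc, na.rm = TRUE),
                 var_test_acc = stats::var(test_acc, na.rm = TRUE),
                 mean_loocv_acc = mean(loocv_acc, na.rm = TRUE),
                 var_loocv_acc = stats::var(loocv_acc, na.rm = TRUE),
                 param_mean = if (!is.null(param_store)) colMeans(param_store, na.rm = TRUE),
                 param_var = if (!is.null(param_store)) apply(param_store, 2L, stats::var, na.rm = TRUE)),
            class = "split_study_result")
}

#' Tolerable replacement-noise level for a target accuracy
#'
#' Under replacement noise, mean test accuracy decays approximately linearly
#' from its no-noise baseline `acc(0)` to the 50% chance level at full
#' replacement: `acc(p) = acc(0) - (acc(0) - 0.5) * p`. Inverting at a target
#' accuracy (e.g. the 80% level often assumed for clinical significance)
#' gives the maximum replacement proportion the classifier can tolerate:
#' `p* = (acc(0) - target) / (acc(0) - 0.5)`. The empirical crossing of the
#' sweep's mean-accuracy curve is returned alongside for comparison.
#'
#' @param sweep A replacement-kind [severity_sweep()] result whose first
#'   level is 0.
#' @param target_accuracy Target accuracy as a fraction, ideally in
#'   `(0.5, acc(0))`. Targets at or above `acc(0)` give `p* = 0`; targets at
#'   or below 0.5 give `p* = 1` (with a message, not an error).
#'
#' @return A list with `p_star` (linear-model estimate), `empirical`
#'   (interpolated crossing of the observed curve, `NA` if never crossed),
#'   and `baseline_accuracy`.
#' @export
tolerable_noise_level <- function(sweep, target_accuracy) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (sweep$kind != "replacement") {
    stop("the linear decay model applies to replacement-kind sweeps",
         call. = FALSE)
  }
  acc0 <- sweep$summary$mean_test_acc[1L]
  p_star <- if (target_accuracy >= acc0) {
    message("target accuracy is at or above the baseline; p* = 0")
    0
  } else if (target_accuracy <= 0.5) {
    message("target accuracy is at or below chance; p* = 1")
    1
  } else {
    (acc0 - target_accuracy) / (acc0 - 0.5)
  }
  lv <- sweep$summary$level
  mu <- sweep$summary$mean_test_acc
  empirical <- NA_real_
  below <- which(mu <= target_accuracy)
  if (length(below) && below[1L] > 1L) {
    i <- below[1L]
    empirical <- lv[i - 1L] + (mu[i - 1L] - target_accuracy) /
      (mu[i - 1L] - mu[i]) * (lv[i] - lv[i - 1L])
  } else if (length(below) && below[1L] == 1L) {
    empirical <- lv[1L]
  }
  list(p_star = p_star, empirical = empirical, baseline_accuracy = acc0)
}

#' Tidy summary of a Monte Carlo result
#'
#' @param results A `sweep_result` or `split_study_result`.
#'
#' @return A data frame: one row per noise level for sweeps (columns
#'   `classifier`, `condition`, `level`, accuracy means/variances) or a
#'   single row for a split study.
#' @export
summarize_result <- function(results) {
  if (inherits(results, "sweep_result")) {
    cbind(data.frame(classifier = results$spec$algorithm,
                     condition = results$kind),
          results$summary)
  } else if (inherits(results, "split_study_result")) {
    data.frame(classifier = results$spec$algorithm,
               condition = "mc_split",
               level = NA_real_,
               mean_test_acc = results$mean_test_acc,
               var_test_acc = results$var_test_acc,
               mean_loocv_acc = results$mean_loocv_acc,
               var_loocv_acc = results$var_loocv_acc)
  } else {
    stop("unsupported result type", call. = FALSE)
  }
}
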