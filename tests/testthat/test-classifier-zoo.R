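algorithms <- c("LDA", "SVM", "RF", "PLSDA", "LOG", "MLP")

test_that("all six algorithms separate the linearly separable toy", {
  toy <- separable_toy(n_per_class = 20, seed = 1)
  std <- standardize(toy)
  x <- std$table$values
  for (alg in algorithms) {
    spec <- classifier_spec(alg)
    fit <- fit_classifier(spec, x, toy$labels, seed = 3)
    expect_equal(mean(predict(fit, x) == toy$labels), 1.0,
                 info = alg)
    # determinism: identical spec + data + seed give identical predictions
    fit2 <- fit_classifier(spec, x, toy$labels, seed = 3)
    expect_identical(predict(fit, x), predict(fit2, x), info = alg)
    # empty input gives empty output
    expect_identical(predict(fit, x[0, , drop = FALSE]), integer(0))
  }
})

test_that("LDA reaches the calibrated baseline on the reference fixture", {
  fx <- reference_fixture()
  split <- make_split(fx$table, seed = 5)
  acc <- robustcheck:::run_one_rep(fx$table, classifier_spec("LDA"), split,
                                   seed = 1)$test_acc
  expect_gte(acc, 0.9)
})

test_that("fitting rejects degenerate inputs", {
  toy <- separable_toy(seed = 2)
  x <- standardize(toy)$table$values
  expect_error(fit_classifier(classifier_spec("LDA"), x, rep(1L, nrow(x))),
               "single class")
  spec <- classifier_spec("LDA", features = c("f1", "nope"))
  expect_error(fit_classifier(spec, x, toy$labels), "nope")
  expect_error(classifier_spec("LDA", hyperparameters = list(bogus = 1)),
               "bogus")
})

test_that("extracted parameters have the declared kind and arity", {
  fx <- planted_small(seed = 4)
  std <- standardize(fx$table)
  x <- std$table$values
  y <- fx$table$labels
  for (alg in algorithms) {
    fit <- fit_classifier(classifier_spec(alg), x, y, seed = 2)
    pv <- extract_params(fit)
    if (alg == "MLP") {
      expect_equal(pv$kind, "none")
      expect_length(pv$entries, 0L)
    } else if (alg == "RF") {
      expect_equal(pv$kind, "importance")
      expect_equal(names(pv$entries), colnames(x))
      expect_true(all(pv$entries >= 0))
      expect_equal(sum(pv$entries), 1, tolerance = 1e-8)
    } else {
      expect_equal(pv$kind, "coefficient")
      expect_equal(names(pv$entries), colnames(x))
      expect_true(all(is.finite(pv$entries)))
    }
  }
})

test_that("a label-independent feature gets a near-zero LDA coefficient", {
  n <- 2000
  dat <- robustcheck:::with_seed(6, {
    y <- rep(0:1, each = n / 2)
    x <- cbind(signal = rnorm(n) + 2 * y, noise = rnorm(n))
    list(x = scale(x), y = y)
  })
  fit <- fit_classifier(classifier_spec("LDA"), dat$x, dat$y, seed = 1)
  w <- fit$params$entries
  expect_lt(abs(w["noise"]), 0.1 * abs(w["signal"]))
})

test_that("one-component PLS-DA agrees with an independent NIPALS oracle", {
  fx <- planted_small(seed = 9)
  std <- standardize(fx$table)
  x <- std$table$values
  y <- fx$table$labels
  fit <- fit_classifier(classifier_spec("PLSDA"), x, y, seed = 1)

  # independent oracle: one NIPALS iteration-to-convergence for a single
  # latent variable, then regression of y on the score
  xc <- scale(x, scale = FALSE)
  yc <- y - mean(y)
  w <- rnorm(ncol(x))
  for (i in 1:200) {
    t_score <- xc %*% w / sum(w^2)
    w_new <- drop(crossprod(xc, yc))
    w_new <- w_new / sqrt(sum(w_new^2))
    if (max(abs(w_new - w)) < 1e-12) break
    w <- w_new
  }
  t_score <- drop(xc %*% w)
  q <- sum(t_score * yc) / sum(t_score^2)
  beta_oracle <- w * q
  expect_equal(unname(fit$params$entries), unname(beta_oracle),
               tolerance = 1e-8)

  # threshold convention: a continuous output of exactly 0.5 goes to class 1
  model <- fit$model
  x_tie <- matrix(0, 1, ncol(x), dimnames = list(NULL, colnames(x)))
  # solve for a point with output exactly at the threshold along beta
  b <- model$beta
  x_tie[1, ] <- model$x_mean + (0.5 - model$y_mean) * b / sum(b^2)
  expect_equal(robustcheck:::pls1_predict(model, x_tie), 1L)
})

test_that("LOOCV accuracy is an exact ratio and behaves at the extremes", {
  toy <- separable_toy(n_per_class = 10, seed = 3)
  x <- standardize(toy)$table$values
  expect_equal(loocv_accuracy(classifier_spec("LDA"), x, toy$labels), 1.0)

  # N = 4: the accuracy is quantized to quarters
  tiny <- omics_table(matrix(c(0, 0.1, 3, 3.1, 1, 2, 1, 2), 4, 2),
                      labels = c(0, 0, 1, 1))
  acc <- suppressWarnings(loocv_accuracy(classifier_spec("LDA"),
                                         scale(tiny$values), tiny$labels))
  expect_true(acc %in% c(0, 0.25, 0.5, 0.75, 1))

  # permuted labels give chance-level LOOCV accuracy
  dat <- robustcheck:::with_seed(8, {
    x <- matrix(rnorm(100 * 3), 100, 3)
    colnames(x) <- paste0("f", 1:3)
    list(x = x, y = sample(rep(0:1, 50)))
  })
  acc <- loocv_accuracy(classifier_spec("LDA"), dat$x, dat$y, seed = 1)
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("wrapper selection enumerates subsets and recovers planted panels", {
  fx <- planted_small(n_case = 20, n_control = 20, f = 6, informative = 2,
                      effect = 3, seed = 5)
  split <- make_split(fx$table, seed = 2)
  res <- wrapper_select_features(fx$table, "LDA", k = 5, split = split)
  expect_equal(res$n_evaluated, 6L)  # C(6,5)
  expect_length(res$spec$features, 5L)

  # k = F returns the full feature set
  res_full <- wrapper_select_features(fx$table, "LDA", k = 6, split = split)
  expect_equal(res_full$spec$features, fx$table$feature_names)

  # planted-signal recovery: a moderate effect keeps single features from
  # saturating LOOCV, so the winning subset must combine the informative ones
  fx2 <- planted_small(n_case = 30, n_control = 30, f = 9, informative = 3,
                       effect = 1.3, seed = 6)
  split2 <- make_split(fx2$table, seed = 3)
  res2 <- wrapper_select_features(fx2$table, "LDA", k = 3, split = split2)
  expect_gte(sum(fx2$informative %in% res2$spec$features), 2L)

  expect_error(wrapper_select_features(fx2$table, "LDA", k = 4, split = split2,
                                       cap = 10), "cap")
})

test_that("prevalence ranking surfaces informative features in the top third", {
  fx <- planted_small(n_case = 20, n_control = 20, f = 9, informative = 3,
                      effect = 3, seed = 7)
  res <- prevalence_rank_features(fx$table, "LDA", k = 3, n_splits = 20,
                                  seed = 4)
  expect_equal(sum(res$prevalence > 0) >= 3, TRUE)
  top_third <- names(res$prevalence)[1:3]
  expect_gte(sum(fx$informative %in% top_third), 2L)
  expect_length(res$spec$features, 3L)
  expect_equal(sort(unique(unlist(lapply(res$winners, length)))), 3L)

  # degenerate two-split study is deterministic
  r2 <- prevalence_rank_features(fx$table, "LDA", k = 3, n_splits = 2, seed = 9)
  r3 <- prevalence_rank_features(fx$table, "LDA", k = 3, n_splits = 2, seed = 9)
  expect_identical(r2$prevalence, r3$prevalence)
})

test_that("prevalence is roughly uniform on uninformative tables", {
  tab <- small_table(n_per_class = 15, f = 6, informative = 0, seed = 10)
  res <- prevalence_rank_features(tab, "LDA", k = 2, n_splits = 50, seed = 3)
  expect_lte(max(res$prevalence) - min(res$prevalence), 0.4)
})

test_that("grid search honors grid order on ties and is reproducible", {
  toy <- separable_toy(n_per_class = 10, seed = 4)
  split <- make_split(toy, seed = 1)
  res <- grid_search_hyperparams(toy, "SVM",
                                 grid = list(cost = c(1, 10, 100)),
                                 split = split)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$hyperparameters$cost, 1)  # first of the tied grid points

  single <- grid_search_hyperparams(toy, "RF", grid = list(ntree = 8L),
                                    split = split, seed = 5)
  expect_equal(single$hyperparameters$ntree, 8L)

  g1 <- grid_search_hyperparams(toy, "RF", grid = list(ntree = c(4L, 16L)),
                                split = split, seed = 5)
  g2 <- grid_search_hyperparams(toy, "RF", grid = list(ntree = c(4L, 16L)),
                                split = split, seed = 5)
  expect_identical(g1, g2)
})

test_that("every algorithm scores near chance on label-permuted data", {
  dat <- robustcheck:::with_seed(12, {
    x <- matrix(rnorm(60 * 4), 60, 4)
    colnames(x) <- paste0("f", 1:4)
    omics_table(x, labels = sample(rep(0:1, 30)))
  })
  for (alg in algorithms) {
    hp <- if (alg == "MLP") list(maxit = 300L) else list()
    spec <- classifier_spec(alg, hyperparameters = hp)
    accs <- vapply(1:50, function(si) {
      split <- make_split(dat, seed = si)
      robustcheck:::run_one_rep(dat, spec, split, seed = si)$test_acc
    }, numeric(1))
    expect_lt(abs(mean(accs) - 0.5), 0.1)
  }
})
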