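test_that("the significance-test triage controls type-I error at 5%", {
  rejections <- 0L
  n_rep <- 1000
  for (r in seq_len(n_rep)) {
    g <- robustcheck:::with_seed(r, list(a = rnorm(30), b = rnorm(30)))
    if (choose_significance_test(g$a, g$b)$p_value < 0.05) {
      rejections <- rejections + 1L
    }
  }
  expect_lt(abs(rejections / n_rep - 0.05), 0.02)
})

test_that("the triage picks sensible branches on archetypal inputs", {
  g <- robustcheck:::with_seed(1, list(a = rnorm(20), b = rnorm(20, mean = 5)))
  res <- choose_significance_test(g$a, g$b)
  expect_lt(res$p_value, 1e-6)
  expect_true(res$test %in% c("student_t", "welch_t"))

  # identical groups (jittered to avoid ties) carry no separation
  a <- robustcheck:::with_seed(2, rnorm(15))
  b <- a + robustcheck:::with_seed(3, rnorm(15, sd = 1e-9))
  expect_gt(choose_significance_test(a, b)$p_value, 0.5)

  # zero-variance group falls through to the rank branch
  res <- choose_significance_test(rep(1, 10), rnorm(10))
  expect_equal(res$test, "mann_whitney")

  # heavily non-normal data take the rank branch
  g <- robustcheck:::with_seed(4, list(a = rexp(50)^3, b = rexp(50)^3))
  expect_equal(choose_significance_test(g$a, g$b)$test, "mann_whitney")

  expect_error(choose_significance_test(1, c(1, 2)), "at least 2")
})

test_that("a perfectly separated feature has FDR 0 (brute-force oracle)", {
  x <- matrix(c(1, 2, 3, 4, 101, 102, 103, 104), ncol = 1)
  tab <- omics_table(x, labels = c(0, 0, 0, 0, 1, 1, 1, 1))
  # independent enumeration: all 8 leave-one-out and 28 leave-two-out
  # subsets keep the groups two orders of magnitude apart, so every t-type
  # p-value is < 0.05
  sets <- c(lapply(1:8, identity), combn(8, 2, simplify = FALSE))
  expect_length(sets, 36L)
  oracle_p <- vapply(sets, function(drop_idx) {
    y <- tab$labels[-drop_idx]
    v <- x[-drop_idx, 1]
    stats::t.test(v[y == 1], v[y == 0])$p.value
  }, numeric(1))
  expect_true(all(oracle_p < 0.05))

  fdr <- compute_feature_fdr(tab, max_leave_out = 2)
  expect_equal(fdr$n_tests, 36L)
  expect_equal(fdr$fdr, 0)
})

test_that("a null feature has FDR near 1 and FDR is an exact integer ratio", {
  tab <- small_table(n_per_class = 50, f = 1, informative = 0, seed = 9)
  fdr <- compute_feature_fdr(tab, max_leave_out = 1)
  expect_equal(fdr$n_tests, 100L)
  expect_gt(fdr$fdr, 0.85)
  expect_equal(fdr$fdr * fdr$n_tests, round(fdr$fdr * fdr$n_tests))
  expect_equal(fdr$fdr, fdr$n_above / fdr$n_tests)
})

test_that("leave-one-out FDR matches per-subset enumeration of the triage", {
  tab <- small_table(n_per_class = 8, f = 2, informative = 1, effect = 1.2,
                     seed = 13)
  fdr <- compute_feature_fdr(tab, max_leave_out = 1)
  for (j in 1:2) {
    above <- 0L
    for (i in seq_len(16)) {
      y <- tab$labels[-i]
      v <- tab$values[-i, j]
      p <- choose_significance_test(v[y == 1], v[y == 0])$p_value
      if (p > 0.05) above <- above + 1L
    }
    expect_equal(fdr$n_above[j], above)
    expect_equal(fdr$fdr[j], above / 16)
  }
})

test_that("the pair-subsampling cap bounds the leave-two-out enumeration", {
  tab <- small_table(n_per_class = 20, f = 1, seed = 2)
  fdr <- compute_feature_fdr(tab, max_leave_out = 2, max_pairs = 50, seed = 3)
  expect_equal(fdr$n_tests, 40L + 50L)
  again <- compute_feature_fdr(tab, max_leave_out = 2, max_pairs = 50, seed = 3)
  expect_identical(fdr, again)
})

test_that("few null features slip through the FDR filter (type-I control)", {
  tab <- small_table(n_per_class = 10, f = 200, informative = 0, seed = 21)
  fdr <- compute_feature_fdr(tab, max_leave_out = 1)
  expect_lte(mean(fdr$fdr <= 0.1), 0.10)
})

test_that("the FDR filter keeps the boundary and rejects empty results", {
  expect_equal(filter_by_fdr(fake_fdr(c(0.0, 0.1, 0.11), total = 100)),
               c("f1", "f2"))
  expect_equal(filter_by_fdr(fake_fdr(rep(0, 4))), paste0("f", 1:4))
  expect_error(filter_by_fdr(fake_fdr(rep(1, 3))), "no significant features")
})

test_that("parallel analysis recovers two planted orthogonal factors", {
  make_two_factor <- function(seed) {
    robustcheck:::with_seed(seed, {
      n <- 200
      scores <- matrix(rnorm(n * 2), n, 2)
      load <- matrix(0, 2, 10)
      load[1, 1:5] <- 0.9
      load[2, 6:10] <- 0.9
      x <- scores %*% load + matrix(rnorm(n * 10, sd = 0.3), n, 10)
      scale(x)
    })
  }
  expect_equal(horns_parallel(make_two_factor(5), n_iter = 200, seed = 1), 2L)
  expect_equal(horns_parallel(make_two_factor(5), n_iter = 200, seed = 1), 2L)

  hits <- 0L
  for (s in 1:50) {
    k <- horns_parallel(make_two_factor(s), n_iter = 150, seed = s + 100)
    if (k == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("pure noise retains no components for nearly all seeds", {
  zeros <- 0L
  for (s in 1:20) {
    x <- robustcheck:::with_seed(s, matrix(rnorm(500 * 10), 500, 10))
    k <- tryCatch(horns_parallel(scale(x), n_iter = 150, seed = s + 500),
                  error = function(e) 0L)
    if (k == 0L) zeros <- zeros + 1L
  }
  expect_gte(zeros, 18L)
  expect_error(horns_parallel(matrix(rnorm(40), 20, 2), n_iter = 50, seed = 1),
               "at least 100")
})

test_that("loading matrices follow the chosen eigenvalue exponent", {
  P <- diag(2)
  A <- compute_loadings(P, c(4, 1), convention = "-1/2")
  expect_equal(unclass(A)[, ], diag(c(0.5, 1)), ignore_attr = TRUE)
  A2 <- compute_loadings(P, c(4, 1), convention = "+1/2")
  expect_equal(unclass(A2)[, ], diag(c(2, 1)), ignore_attr = TRUE)

  # sign pattern is convention-invariant for arbitrary inputs
  Pr <- robustcheck:::with_seed(3, qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:3])
  ev <- c(3.2, 1.5, 0.4)
  s1 <- sign(compute_loadings(Pr, ev, "-1/2"))
  s2 <- sign(compute_loadings(Pr, ev, "+1/2"))
  expect_equal(unclass(s1), unclass(s2), ignore_attr = TRUE)

  expect_error(compute_loadings(P, c(1, 0)), "strictly positive")
})

test_that("per-cluster silhouettes match hand computations", {
  # 1-D loadings {0,1} vs {5,6}: a1 = 1, b1 = 5, s1 = 0.8
  A <- matrix(c(0, 1, 5, 6), ncol = 1)
  rownames(A) <- paste0("f", 1:4)
  sol <- cluster_loadings(A, k_range = 2, seed = 1)
  expect_equal(sol$k, 2L)
  expect_equal(sort(sol$silhouettes$a), c(1, 1))
  expect_equal(sort(sol$silhouettes$b), c(5, 5))
  expect_equal(sol$silhouettes$silhouette, c(0.8, 0.8))

  # coincident points far apart: a = 0 so s = 1 for both clusters
  A2 <- matrix(c(0, 0, 5, 5, 0, 0, 5, 5), 4, 2)
  rownames(A2) <- paste0("g", 1:4)
  sol2 <- cluster_loadings(A2, k_range = 2, seed = 1)
  expect_equal(sol2$silhouettes$silhouette, c(1, 1))

  # a_c = b_c gives s_c = 0
  d <- matrix(1, 4, 4); diag(d) <- 0
  sil <- robustcheck:::cluster_silhouettes(d, c(1L, 1L, 2L, 2L))
  expect_equal(sil$silhouette, c(0, 0))

  expect_error(cluster_loadings(matrix(1:2, 2, 1)), "at least 3")
})

test_that("tight clusters are pruned to their three most central members", {
  # hand-built solution: tight cluster of 5 near the origin (s = 0.9),
  # loose cluster of 4 (s = 0.2)
  A <- rbind(matrix(c(0.00, 0.01, -0.01, 0.02, -0.02), 5, 1),
             matrix(c(3, 6, 9, 12), 4, 1))
  rownames(A) <- paste0("m", 1:9)
  sol <- structure(list(
    k = 2L,
    labels = setNames(rep(1:2, c(5L, 4L)), rownames(A)),
    silhouettes = data.frame(cluster = 1:2, a = c(0.02, 5), b = c(7.5, 7.5),
                             silhouette = c(0.9, 0.2)),
    centers = matrix(c(0, 7.5), 2, 1), A = A
  ), class = "cluster_solution")

  kept <- prune_tight_clusters(sol, silhouette_threshold = 0.5)
  expect_length(kept, 3L + 4L)
  expect_true(all(c("m1", "m2", "m3") %in% kept))  # closest to the centroid
  expect_false(any(c("m4", "m5") %in% kept))

  # threshold above every silhouette: nothing is pruned
  expect_length(prune_tight_clusters(sol, silhouette_threshold = 1.01), 9L)

  # a tight cluster of exactly three contributes all members
  sol3 <- sol
  sol3$labels <- setNames(rep(1:2, c(3L, 6L)), rownames(A))
  expect_length(prune_tight_clusters(sol3, silhouette_threshold = 0.5), 9L)
})

test_that("the variance probe matches its analytic oracle and scales to 8", {
  w <- c(a = 2, b = 1, c = 0.9)
  probe <- robustcheck:::variance_probe(w, n_draws = 100000, seed = 5)
  # analytic: Var(w Z) = w^2, scaled = 8 w^2 / max w^2 = (8, 2, 1.62)
  expect_equal(unname(probe$scaled), c(8, 2, 1.62), tolerance = 0.05)
  expect_equal(max(probe$scaled), 8)
  expect_lt(max(abs(probe$raw - w^2) / w^2), 0.05)
})

test_that("the logistic variance screen keeps features by relative weight", {
  tab <- small_table(n_per_class = 100, f = 4, informative = 2, effect = 2,
                     seed = 31)
  std <- standardize(tab)$table
  res <- logistic_variance_screen(std$values, std$labels, seed = 2)
  expect_equal(max(res$scaled_variances), 8)
  # retention is equivalent to |w_f| >= 0.5 max|w| up to Monte Carlo error
  analytic <- names(res$weights)[abs(res$weights) >= 0.5 * max(abs(res$weights))]
  expect_setequal(res$features_kept, analytic)
  expect_true(all(res$features_kept %in% colnames(std$values)))

  # a single remaining feature always scales to 8 and is retained
  one <- logistic_variance_screen(std$values[, 1, drop = FALSE], std$labels,
                                  seed = 2)
  expect_equal(unname(one$scaled_variances), 8)
  expect_length(one$features_kept, 1L)
})

test_that("the full screen recovers planted features and only removes", {
  fx <- reference_fixture()
  res <- run_factor_analysis(fx$table, max_pairs = 150, horn_iter = 150,
                             seed = 17)
  expect_true(all(res$F_star %in% res$F_doubleprime))
  expect_true(all(res$F_doubleprime %in% res$F_prime))
  expect_true(all(res$F_prime %in% fx$table$feature_names))
  expect_gte(sum(fx$informative %in% res$F_star), 4L)
  nulls <- setdiff(fx$table$feature_names, fx$informative)
  expect_lte(sum(nulls %in% res$F_star), 2L)

  again <- run_factor_analysis(fx$table, max_pairs = 150, horn_iter = 150,
                               seed = 17)
  expect_identical(res[c("F_prime", "F_doubleprime", "F_star")],
                   again[c("F_prime", "F_doubleprime", "F_star")])
})

test_that("a table with no informative features fails the FDR stage", {
  tab <- small_table(n_per_class = 15, f = 6, informative = 0, seed = 4)
  expect_error(run_factor_analysis(tab, max_leave_out = 1, seed = 1),
               "no significant features")
})
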