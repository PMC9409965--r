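#' Choose and apply a two-sample significance test
#'
#' Triage for the per-feature group comparison: Shapiro-Wilk normality is
#' checked on both groups at level `alpha`; if both pass, Levene's test
#' decides between Student's t (equal variances) and Welch's t, otherwise the
#' Mann-Whitney U test is used. A group with zero variance falls through to
#' the rank-based branch. Groups of only 2 values (as arise in leave-two-out
#' subsets of small classes) skip the normality check and take the
#' parametric branch, since rank tests cannot reach p < 0.05 at such sizes.
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @param alpha Level for the normality and variance-equality checks
#'   (default 0.05).
#'
#' @return A list with `test` (one of `"student_t"`, `"welch_t"`,
#'   `"mann_whitney"`) and the two-sided `p_value`.
#' @export
choose_significance_test <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("both groups need at least 2 values", call. = FALSE)
  }
  if (stats::var(group_a) == 0 || stats::var(group_b) == 0) {
    normal_branch <- FALSE
  } else if (length(group_a) < 3L || length(group_b) < 3L ||
             length(group_a) > 5000L || length(group_b) > 5000L) {
    normal_branch <- TRUE  # too few values to assess normality
  } else {
    sw_a <- stats::shapiro.test(group_a)$p.value
    sw_b <- stats::shapiro.test(group_b)$p.value
    normal_branch <- (sw_a > alpha && sw_b > alpha)
  }
  if (normal_branch) {
    vals <- c(group_a, group_b)
    grp <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
    lev_p <- car::leveneTest(vals, grp)[["Pr(>F)"]][1L]
    equal_var <- is.finite(lev_p) && lev_p > alpha
    res <- stats::t.test(group_a, group_b, var.equal = equal_var)
    list(test = if (equal_var) "student_t" else "welch_t",
         p_value = res$p.value)
  } else {
    res <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = FALSE))
    p <- res$p.value
    if (is.na(p)) p <- 1  # both groups constant and identical
    list(test = "mann_whitney", p_value = p)
  }
}

#' Leave-out false discovery rate per feature
#'
#' For each feature, a two-group p-value (via
#' [choose_significance_test()]) is computed on every leave-one-out subset of
#' the samples and, at depth 2, on every leave-two-out subset. The feature's
#' FDR is the exact ratio (count of p-values above `p_threshold`) / (total
#' p-values): a stability-of-significance score, not a multiple-testing
#' correction. Features whose significance survives every deletion get
#' FDR 0; features whose apparent significance hinges on a few samples get a
#' large FDR.
#'
#' @param table An [omics_table()] (standardization does not change the
#'   p-values of the tests used).
#' @param max_leave_out 1 or 2 (default 2): whether leave-two-out subsets are
#'   included.
#' @param p_threshold Significance cutoff counted against a feature
#'   (default 0.05).
#' @param alpha Level for the test-selection triage (default 0.05).
#' @param max_pairs Optional cap on the number of leave-two-out pairs; when
#'   the full N(N-1)/2 enumeration exceeds it, a seeded uniform subsample of
#'   pairs is used. Default `Inf` (full enumeration, intended for N up to a
#'   few hundred).
#' @param seed Seed for the pair subsample.
#'
#' @return A `fdr_result` data frame with columns `feature`, `n_tests`,
#'   `n_above` and `fdr`, one row per feature in input order.
#' @export
compute_feature_fdr <- function(table, max_leave_out = 2L, p_threshold = 0.05,
                                alpha = 0.05, max_pairs = Inf, seed = 1L) {
  stopifnot(inherits(table, "omics_table"))
  if (!max_leave_out %in% c(1L, 2L)) {
    stop("`max_leave_out` must be 1 or 2", call. = FALSE)
  }
  n <- nrow(table$values)
  leave_sets <- lapply(seq_len(n), function(i) i)
  if (max_leave_out == 2L) {
    pairs <- utils::combn(n, 2L)
    if (ncol(pairs) > max_pairs) {
      keep <- with_seed(seed, sample.int(ncol(pairs), max_pairs))
      pairs <- pairs[, keep, drop = FALSE]
    }
    leave_sets <- c(leave_sets, lapply(seq_len(ncol(pairs)),
                                       function(i) pairs[, i]))
  }
  labels <- table$labels
  out <- data.frame(feature = table$feature_names,
                    n_tests = 0L, n_above = 0L, fdr = NA_real_,
                    stringsAsFactors = FALSE)
  skipped <- 0L
  for (j in seq_along(table$feature_names)) {
    col <- table$values[, j]
    total <- 0L
    above <- 0L
    for (drop_idx in leave_sets) {
      y <- labels[-drop_idx]
      if (length(unique(y)) < 2L || min(table(y)) < 2L) {
        skipped <- skipped + 1L
        next
      }
      v <- col[-drop_idx]
      p <- choose_significance_test(v[y == 1L], v[y == 0L],
                                    alpha = alpha)$p_value
      total <- total + 1L
      if (p > p_threshold) above <- above + 1L
    }
    out$n_tests[j] <- total
    out$n_above[j] <- above
    out$fdr[j] <- above / total
  }
  if (skipped > 0L) {
    message(sprintf("compute_feature_fdr: %d leave-out set(s) skipped (a class became too small)",
                    skipped))
  }
  class(out) <- c("fdr_result", "data.frame")
  out
}

#' Filter features by leave-out FDR
#'
#' Retains features with FDR at or below `threshold` (features with FDR
#' strictly greater than the threshold are removed), preserving input order.
#'
#' @param fdr A `fdr_result` from [compute_feature_fdr()].
#' @param threshold FDR cutoff (default 0.1).
#'
#' @return Character vector of retained feature names (the set F').
#' @export
filter_by_fdr <- function(fdr, threshold = 0.1) {
  stopifnot(inherits(fdr, "fdr_result"))
  kept <- fdr$feature[fdr$fdr <= threshold]
  if (length(kept) == 0L) {
    stop("no significant features: every feature exceeds the FDR threshold",
         call. = FALSE)
  }
  kept
}

#' Horn's parallel analysis for component retention
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' rank-wise percentile of eigenvalues from `n_iter` same-shape standard
#' normal matrices; the retained component count k is the length of the
#' leading run of observed eigenvalues exceeding their null percentile.
#'
#' @param x Standardized numeric matrix (samples x features).
#' @param n_iter Number of null matrices (default 1000, minimum 100).
#' @param percentile Null eigenvalue percentile (default 0.95).
#' @param seed Integer seed.
#'
#' @return Integer k >= 1. If no observed eigenvalue exceeds its null
#'   percentile an error explains that no retained structure was found.
#' @export
horns_parallel <- function(x, n_iter = 1000L, percentile = 0.95, seed = 1L) {
  x <- as.matrix(x)
  if (n_iter < 100L) stop("`n_iter` must be at least 100", call. = FALSE)
  n <- nrow(x)
  m <- ncol(x)
  obs <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  null_eigs <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      z <- matrix(stats::rnorm(n * m), n, m)
      eigen(stats::cor(z), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(m))
  })
  thresh <- apply(null_eigs, 1L, stats::quantile, probs = percentile)
  exceeds <- obs > thresh
  k <- if (exceeds[1L]) {
    run <- rle(exceeds)
    run$lengths[1L]
  } else {
    0L
  }
  if (k == 0L) {
    stop(paste("parallel analysis retained no components: no eigenvalue",
               "exceeds the random-data percentile, so the data show no",
               "correlation structure beyond noise"), call. = FALSE)
  }
  as.integer(k)
}

#' Factor loading matrix from retained components
#'
#' Builds the m x k loading matrix `A = P V^(-1/2)` from the eigenvectors P
#' and the diagonal eigenvalue matrix V of the retained components. The
#' `-1/2` exponent follows the source procedure as written;
#' `convention = "+1/2"` gives the textbook loading definition
#' `A = P V^(+1/2)`. Both share the same sign pattern (the diagonal scaling
#' is positive), so the downstream clustering is affected only through
#' column scale.
#'
#' @param eigenvectors m x k matrix with orthonormal columns.
#' @param eigenvalues Length-k vector of strictly positive eigenvalues.
#' @param convention `"-1/2"` (default, as-written) or `"+1/2"`.
#'
#' @return A `loading_matrix`: the m x k matrix `A` with attributes
#'   `convention`, `eigenvalues`, and `eigenvectors`.
#' @export
compute_loadings <- function(eigenvectors, eigenvalues,
                             convention = c("-1/2", "+1/2")) {
  convention <- match.arg(convention)
  P <- as.matrix(eigenvectors)
  if (length(eigenvalues) != ncol(P)) {
    stop("one eigenvalue per eigenvector column is required", call. = FALSE)
  }
  if (any(eigenvalues <= 0)) {
    stop("eigenvalues must be strictly positive", call. = FALSE)
  }
  expo <- if (convention == "-1/2") -0.5 else 0.5
  A <- P %*% diag(eigenvalues^expo, nrow = length(eigenvalues))
  rownames(A) <- rownames(P)
  structure(A, class = c("loading_matrix", "matrix"),
            convention = convention, eigenvalues = eigenvalues,
            eigenvectors = P)
}

# Per-cluster silhouette from a distance matrix and integer labels:
# a_c = mean pairwise distance within cluster c (0 for singletons),
# b_c = smallest mean cross-cluster distance from c to another cluster,
# s_c = (b_c - a_c) / max(a_c, b_c).
cluster_silhouettes <- function(d, labels) {
  ks <- sort(unique(labels))
  a <- b <- s <- numeric(length(ks))
  for (i in seq_along(ks)) {
    members <- which(labels == ks[i])
    a[i] <- if (length(members) > 1L) {
      sub <- d[members, members, drop = FALSE]
      mean(sub[upper.tri(sub)])
    } else 0
    cross <- vapply(ks[ks != ks[i]], function(k2) {
      mean(d[members, which(labels == k2), drop = FALSE])
    }, numeric(1))
    b[i] <- min(cross)
    s[i] <- if (max(a[i], b[i]) == 0) 0 else (b[i] - a[i]) / max(a[i], b[i])
  }
  data.frame(cluster = ks, a = a, b = b, silhouette = s)
}

#' Cluster factor loadings with k-means
#'
#' Clusters the rows of the loading matrix (one point per feature) with
#' seeded k-means over a range of cluster counts, scoring each solution by
#' the mean per-cluster silhouette `s_c = (b_c - a_c) / max(a_c, b_c)`,
#' where `a_c` is the mean within-cluster pairwise distance and `b_c` the
#' mean distance to the nearest other cluster. The k maximizing the mean
#' silhouette wins (smallest k on ties). Tight clusters (large `s_c`)
#' indicate groups of near-duplicate features.
#'
#' @param A A [compute_loadings()] matrix (m features x k components), m >= 3.
#' @param k_range Candidate cluster counts, a subset of `2:(m-1)`; default
#'   `2:min(10, m - 1)`.
#' @param seed Integer seed.
#' @param nstart Random restarts per k (default 10; best inertia kept).
#'
#' @return A `cluster_solution`: list with `k`, `labels` (named integer
#'   vector over features, values `1:k`), `silhouettes` (per-cluster data
#'   frame with `a`, `b`, `silhouette`), `centers`, and the clustered matrix
#'   `A`.
#' @export
cluster_loadings <- function(A, k_range = NULL, seed = 1L, nstart = 10L) {
  A <- as.matrix(A)
  m <- nrow(A)
  if (m < 3L) stop("at least 3 features are required for clustering",
                   call. = FALSE)
  if (is.null(k_range)) k_range <- 2:min(10L, m - 1L)
  k_range <- k_range[k_range >= 2L & k_range <= m - 1L]
  if (length(k_range) == 0L) stop("`k_range` must lie within [2, m-1]",
                                  call. = FALSE)
  d <- as.matrix(stats::dist(A))
  best <- NULL
  best_score <- -Inf
  for (k in k_range) {
    km <- with_seed(derive_seed(seed, k),
                    stats::kmeans(A, centers = k, nstart = nstart,
                                  iter.max = 50L))
    sil <- cluster_silhouettes(d, km$cluster)
    score <- mean(sil$silhouette)
    if (score > best_score + 1e-12) {
      best_score <- score
      best <- list(k = k, km = km, sil = sil)
    }
  }
  structure(list(k = best$k,
                 labels = stats::setNames(best$km$cluster, rownames(A)),
                 silhouettes = best$sil,
                 centers = best$km$centers,
                 A = A,
                 mean_silhouette = best_score),
            class = "cluster_solution")
}

#' Prune tightly knit loading clusters
#'
#' Clusters with silhouette at or above `silhouette_threshold` are treated as
#' groups of excessively similar (redundant) features and contribute only
#' their `keep_per_cluster` members closest to the cluster centroid (ties
#' broken by lowest feature index); looser clusters contribute all members.
#'
#' @param clusters A [cluster_loadings()] solution.
#' @param silhouette_threshold Tightness cutoff (default 0.5).
#' @param keep_per_cluster Members kept from a tight cluster (default 3).
#'
#' @return Character vector of surviving feature names (the set F''), in the
#'   original feature order.
#' @export
prune_tight_clusters <- function(clusters, silhouette_threshold = 0.5,
                                 keep_per_cluster = 3L) {
  stopifnot(inherits(clusters, "cluster_solution"))
  feats <- names(clusters$labels)
  keep <- logical(length(feats))
  for (i in seq_len(nrow(clusters$silhouettes))) {
    cl <- clusters$silhouettes$cluster[i]
    members <- which(clusters$labels == cl)
    if (clusters$silhouettes$silhouette[i] >= silhouette_threshold &&
        length(members) > keep_per_cluster) {
      centroid <- clusters$centers[cl, ]
      dists <- sqrt(colSums((t(clusters$A[members, , drop = FALSE]) -
                               centroid)^2))
      ord <- order(dists, members)  # tie-break: lowest feature index
      keep[members[ord[seq_len(keep_per_cluster)]]] <- TRUE
    } else {
      keep[members] <- TRUE
    }
  }
  feats[keep]
}

#' Logistic variance screen
#'
#' Fits a logistic model on all remaining features, giving a weight vector
#' `w`. Each feature's relevance is probed by replacing its values with
#' standard-normal draws while all other features are zero and measuring the
#' variance of the continuous output `w %*% x` (analytically `w_f^2`). The
#' variances are rescaled so the largest equals 8, and features below 2 on
#' this scale are dropped: on a standard normal, a variance of 8 corresponds
#' to a standard deviation of about 2.83, within which ~99.8% of the mass
#' lies, so the 8-scale spans the plausible output range and the cut at 2
#' removes features contributing little output variation.
#'
#' @param x Standardized numeric matrix restricted to the surviving features.
#' @param y Integer 0/1 labels.
#' @param n_draws Monte Carlo draws per feature probe (default 100000).
#' @param seed Integer seed.
#'
#' @return A list with `weights` (named logistic weights), `raw_variances`,
#'   `scaled_variances` (max exactly 8), and `features_kept` (the set F*:
#'   scaled variance >= 2, input order preserved).
#' @export
logistic_variance_screen <- function(x, y, n_draws = 100000L, seed = 1L) {
  x <- as.matrix(x)
  feats <- colnames(x)
  model <- with_seed(seed, fit_ridge_logistic(x, y))
  w <- if (model$engine == "glmnet") {
    drop(as.matrix(stats::coef(model$fit, s = model$lambda)))[-1L]
  } else {
    stats::coef(model$fit)[-1L]
  }
  w <- stats::setNames(unname(w), feats)
  if (all(w == 0)) stop("all logistic weights are zero", call. = FALSE)
  probe <- variance_probe(w, n_draws = n_draws, seed = seed)
  list(weights = w, raw_variances = probe$raw,
       scaled_variances = probe$scaled,
       features_kept = feats[probe$scaled >= 2])
}

# Monte Carlo output-variance probe for a weight vector: the variance of
# w_f * Z with Z ~ N(0,1) per feature (analytically w_f^2), rescaled so the
# largest equals 8.
variance_probe <- function(w, n_draws = 100000L, seed = 1L) {
  raw <- vapply(seq_along(w), function(j) {
    z <- with_seed(derive_seed(seed, j), stats::rnorm(n_draws))
    stats::var(w[j] * z)
  }, numeric(1))
  names(raw) <- names(w)
  list(raw = raw, scaled = 8 * raw / max(raw))
}

#' Run the full factor-analysis feature screen
#'
#' Executes the three-stage screen: (1) leave-out FDR filtering at
#' `fdr_threshold` giving F'; (2) PCA on the survivors with Horn's parallel
#' analysis choosing the component count, loading-matrix construction, and
#' k-means pruning of tight loading clusters giving F''; (3) the logistic
#' variance screen giving F*. Every intermediate result is returned so that
#' each removal can be audited. The resulting F* is a reference set of
#' statistically meaningful features against which a classifier's inputs can
#' be compared; it is not itself a feature-subset selection.
#'
#' @param table An [omics_table()].
#' @param fdr_threshold FDR cutoff for stage 1 (default 0.1).
#' @param max_leave_out,max_pairs Passed to [compute_feature_fdr()].
#' @param alpha Level for the test-selection triage.
#' @param horn_iter,horn_percentile Passed to [horns_parallel()].
#' @param exponent_convention Passed to [compute_loadings()].
#' @param silhouette_threshold,keep_per_cluster Passed to
#'   [prune_tight_clusters()].
#' @param k_range Passed to [cluster_loadings()].
#' @param n_draws Passed to [logistic_variance_screen()].
#' @param seed Master seed; each stochastic stage derives its own stream.
#'
#' @return A `screen_result`: list with `F_prime`, `F_doubleprime`, `F_star`,
#'   `fdr`, `n_components`, `loadings`, `clusters` (`NULL` when fewer than 3
#'   features reach the clustering stage), `weights`, `scaled_variances`, and
#'   the configuration used.
#' @export
run_factor_analysis <- function(table, fdr_threshold = 0.1, max_leave_out = 2L,
                                max_pairs = Inf, alpha = 0.05,
                                horn_iter = 1000L, horn_percentile = 0.95,
                                exponent_convention = "-1/2",
                                silhouette_threshold = 0.5,
                                keep_per_cluster = 3L, k_range = NULL,
                                n_draws = 100000L, seed = 1L) {
  stopifnot(inherits(table, "omics_table"))
  std <- standardize(table)$table

  fdr <- compute_feature_fdr(std, max_leave_out = max_leave_out,
                             alpha = alpha, max_pairs = max_pairs,
                             seed = derive_seed(seed, 1L))
  f_prime <- filter_by_fdr(fdr, threshold = fdr_threshold)

  x_prime <- std$values[, f_prime, drop = FALSE]
  clusters <- NULL
  loadings <- NULL
  n_comp <- NA_integer_
  if (length(f_prime) >= 3L) {
    eig <- eigen(stats::cor(x_prime), symmetric = TRUE)
    n_comp <- horns_parallel(x_prime, n_iter = horn_iter,
                             percentile = horn_percentile,
                             seed = derive_seed(seed, 2L))
    P <- eig$vectors[, seq_len(n_comp), drop = FALSE]
    rownames(P) <- f_prime
    loadings <- compute_loadings(P, eig$values[seq_len(n_comp)],
                                 convention = exponent_convention)
    clusters <- cluster_loadings(loadings, k_range = k_range,
                                 seed = derive_seed(seed, 3L))
    f_doubleprime <- prune_tight_clusters(clusters,
                                          silhouette_threshold = silhouette_threshold,
                                          keep_per_cluster = keep_per_cluster)
  } else {
    message("fewer than 3 features after FDR filtering; clustering skipped")
    f_doubleprime <- f_prime
  }

  screen <- logistic_variance_screen(std$values[, f_doubleprime, drop = FALSE],
                                     std$labels, n_draws = n_draws,
                                     seed = derive_seed(seed, 4L))

  structure(list(F_prime = f_prime, F_doubleprime = f_doubleprime,
                 F_star = screen$features_kept,
                 fdr = fdr, n_components = n_comp, loadings = loadings,
                 clusters = clusters, weights = screen$weights,
                 scaled_variances = screen$scaled_variances,
                 config = list(fdr_threshold = fdr_threshold,
                               max_leave_out = max_leave_out,
                               silhouette_threshold = silhouette_threshold,
                               keep_per_cluster = keep_per_cluster,
                               exponent_convention = exponent_convention,
                               seed = seed)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("factor-analysis screen: %d -> %d (FDR) -> %d (clusters) -> %d (variance)\n",
              nrow(x$fdr), length(x$F_prime), length(x$F_doubleprime),
              length(x$F_star)))
  cat("F*:", paste(x$F_star, collapse = ", "), "\n")
  invisible(x)
}
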