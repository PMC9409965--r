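# Fixtures built in code; every helper is deterministic given its seed.

# Minimal two-class table: f independent features, the first `informative`
# of which are shifted by `effect` in the case class.
small_table <- function(n_per_class = 10, f = 3, informative = 1,
                        effect = 3, seed = 1) {
  robustcheck:::with_seed(seed, {
    n <- 2 * n_per_class
    x <- matrix(rnorm(n * f), n, f)
    labels <- rep(c(1L, 0L), each = n_per_class)
    if (informative > 0) {
      x[labels == 1L, seq_len(informative)] <-
        x[labels == 1L, seq_len(informative)] + effect
    }
    omics_table(x, labels = labels)
  })
}

# Linearly separable 2-D toy: classes centered at (-3,-3) and (3,3).
separable_toy <- function(n_per_class = 20, seed = 1) {
  robustcheck:::with_seed(seed, {
    n <- 2 * n_per_class
    centers <- rbind(c(3, 3), c(-3, -3))
    labels <- rep(c(1L, 0L), each = n_per_class)
    x <- centers[2L - labels, ] + matrix(rnorm(n * 2, sd = 0.3), n, 2)
    colnames(x) <- c("f1", "f2")
    omics_table(x, labels = labels)
  })
}

# Downsized planted-signal dataset for the heavier search-based tests.
planted_small <- function(n_case = 30, n_control = 30, f = 9, informative = 3,
                          effect = 2.5, seed = 1) {
  generate_dataset(synth_config(n_case = n_case, n_control = n_control,
                                n_features = f, n_informative = informative,
                                effect_size = effect, seed = seed))
}

# Hand-built fdr_result for boundary tests.
fake_fdr <- function(fdrs, total = 10L) {
  out <- data.frame(feature = paste0("f", seq_along(fdrs)),
                    n_tests = total, n_above = as.integer(round(fdrs * total)),
                    fdr = fdrs, stringsAsFactors = FALSE)
  class(out) <- c("fdr_result", "data.frame")
  out
}
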