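#' Specify a noise corruption recipe
#'
#' @param kind `"replacement"` (a proportion `level` = p of each feature
#'   column is replaced by draws from a normal fitted to the clean column) or
#'   `"gaussian"` (zero-mean noise with standard deviation `level` = s times
#'   the column standard deviation is added elementwise).
#' @param level Noise level in `[0, 1]`: the replacement proportion p or the
#'   dampening factor s.
#' @param clip_negative Set corrupted values below zero to zero, as is
#'   appropriate for concentration data. Default `TRUE` for Gaussian noise
#'   (where the clipping rule originates) and `FALSE` for replacement noise.
#' @param seed Integer seed.
#'
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(kind = c("replacement", "gaussian"), level,
                       clip_negative = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(level) || level < 0 || level > 1) {
    stop("`level` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(clip_negative)) clip_negative <- (kind == "gaussian")
  structure(list(kind = kind, level = level,
                 clip_negative = isTRUE(clip_negative), seed = as.integer(seed)),
            class = "noise_spec")
}

#' Corrupt a table with replacement noise
#'
#' For each feature column, the mean and standard deviation (n-1 denominator)
#' are computed from the clean column; `v = round(p * N)` positions are then
#' chosen uniformly without replacement and each is overwritten by an
#' independent draw from `N(mean, sd^2)`. As p grows the column's information
#' content approaches pure noise, so any classifier's accuracy is driven
#' toward 50%. Applied to raw (pre-standardization) values.
#'
#' @param table An [omics_table()].
#' @param p Proportion of values to replace per column, in `[0, 1]`.
#' @param seed Integer seed; each column uses an independent derived stream.
#' @param clip_negative Clip replaced values below zero to zero
#'   (default `FALSE`).
#'
#' @return The corrupted [omics_table()]; labels, identifiers and shape are
#'   untouched. `p = 0` returns the input bit-exactly.
#' @export
replacement_corrupt <- function(table, p, seed = 1L, clip_negative = FALSE) {
  stopifnot(inherits(table, "omics_table"))
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  x <- table$values
  n <- nrow(x)
  v <- round(p * n)  # round-half-to-even
  if (v == 0L) return(table)
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    mu <- mean(col)
    sdev <- stats::sd(col)
    repl <- with_seed(derive_seed(seed, j), {
      pos <- sample.int(n, v)
      list(pos = pos, draws = stats::rnorm(v, mean = mu, sd = sdev))
    })
    draws <- repl$draws
    if (clip_negative) draws <- pmax(draws, 0)
    x[repl$pos, j] <- draws
  }
  out <- table
  out$values <- x
  out
}

#' Corrupt a table with dampened additive Gaussian noise
#'
#' Adds i.i.d. draws from `N(0, (s * sd_f)^2)` to each feature column, where
#' `sd_f` is the clean column's standard deviation and s the dampening
#' factor. Models systematic measurement error such as instrument drift.
#' Applied to raw (pre-standardization) values.
#'
#' @param table An [omics_table()].
#' @param s Dampening factor scaling the noise standard deviation.
#' @param clip_negative Set corrupted values below zero to zero
#'   (default `TRUE`, appropriate for concentration data).
#' @param seed Integer seed.
#'
#' @return The corrupted [omics_table()]. `s = 0` returns the input
#'   bit-exactly.
#' @export
gaussian_corrupt <- function(table, s, clip_negative = TRUE, seed = 1L) {
  stopifnot(inherits(table, "omics_table"))
  if (s < 0) stop("`s` must be non-negative", call. = FALSE)
  if (s == 0) return(table)
  x <- table$values
  n <- nrow(x)
  for (j in seq_len(ncol(x))) {
    sdev <- stats::sd(x[, j])
    noise <- with_seed(derive_seed(seed, j), stats::rnorm(n, 0, s * sdev))
    x[, j] <- x[, j] + noise
  }
  if (clip_negative) x[x < 0] <- 0
  out <- table
  out$values <- x
  out
}

#' Apply a noise specification to a table
#'
#' Dispatches to [replacement_corrupt()] or [gaussian_corrupt()] according to
#' the spec's `kind` and records the spec in the result's `noise_spec`
#' attribute.
#'
#' @param table An [omics_table()].
#' @param spec A [noise_spec()].
#'
#' @return The corrupted [omics_table()].
#' @export
corrupt <- function(table, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  out <- switch(spec$kind,
    replacement = replacement_corrupt(table, p = spec$level, seed = spec$seed,
                                      clip_negative = spec$clip_negative),
    gaussian = gaussian_corrupt(table, s = spec$level,
                                clip_negative = spec$clip_negative,
                                seed = spec$seed),
    stop("unknown noise kind: ", spec$kind, call. = FALSE)
  )
  attr(out, "noise_spec") <- spec
  out
}
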