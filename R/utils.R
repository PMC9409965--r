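#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules. None of these are exported.

# Evaluate `expr` under a fixed RNG seed without clobbering the caller's
# random stream. All user-facing randomness in the package goes through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic substream seed derived from a master seed plus counters
# (level index, repetition index, ...). Keeps Monte Carlo runs reproducible
# and order-independent: rep r at level l always sees the same stream no
# matter how many reps ran before it. Result stays inside the 32-bit
# integer range set.seed() accepts.
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), vapply(list(...), as.numeric, numeric(1)))
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + p + 1) %% 2147483647
  }
  as.integer(h)
}

# Column standard deviation with the n-1 denominator.
col_sds <- function(x) {
  apply(x, 2, stats::sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
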