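# Internal helpers shared across modules.

# Run `code` under a local RNG state seeded with `seed`, restoring the caller's
# state afterwards so library functions never perturb user-level randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Min-max rescaling to the unit interval
#'
#' Rescales a numeric array linearly so its minimum maps to 0 and its maximum
#' to 1. A constant array (no dynamic range) maps to all zeros, which is the
#' degenerate-input convention used throughout the spectrogram pipeline.
#'
#' @param x numeric vector or matrix.
#' @return object of the same shape with values in \[0, 1\].
#' @export
rescale01 <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("rescale01: non-finite values")
  if (rng[2] - rng[1] <= 0) {
    x[] <- 0
    return(x)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
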