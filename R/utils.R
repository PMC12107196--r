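#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all reported percentages, so that
#' e.g. 20.65 prints as 20.7. `base::round()` rounds half to even, which does
#' not match how clinical tables are typically reported.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `code` under a fixed RNG seed without touching the caller's RNG state.
# All stochastic functions in the package route their randomness through this
# (via an explicit `seed` argument); nothing relies on ambient global state.
with_rng <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# stop() with a consistent error class, so tests can assert on conditions
# rather than message wording.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "edrisk_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
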