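# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Every generator in the package draws its randomness from a stream derived
#' from a single master seed and a small integer counter, so that one seed
#' reproduces an entire simulated cohort byte for byte while the individual
#' generators stay independent of call order.
#'
#' @param seed master seed (integer).
#' @param stream non-negative integer identifying the consumer.
#' @return an integer seed in [0, 2^31 - 2].
#' @keywords internal
fan_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # affine hash mod the Mersenne prime 2^31 - 1; keeps results in int range
  s <- (abs(as.double(seed)) %% 2147483647)
  as.integer((s * 48271 + as.double(stream) * 16807 + 1) %% 2147483647)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# population (divide-by-n) standard deviation; the package standardizes
# scores and expression with this convention throughout
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

# standardize to zero mean, unit population variance; constant input -> zeros
standardize <- function(x) {
  s <- pop_sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
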