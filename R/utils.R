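#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used by
#' most reporting software), unlike [round()] which rounds half to even.
#' A tiny epsilon guards against binary representation of values that are
#' exact halves in decimal.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Derive a per-stream seed from a master seed
#'
#' All randomness in the package flows from one master seed; each generator
#' draws from its own stream so modules can be regenerated independently
#' without perturbing each other. Streams are separated by a fixed
#' multiplicative hash kept below 2^31.
#'
#' @param seed master seed (integer).
#' @param stream small non-negative integer identifying the consumer.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- (abs(seed) %% 2147483647) + 1
  as.integer((s * 48271 + stream * 69621) %% 2147483647)
}

# internal: stop with a consistent prefix for user input errors
.fail <- function(...) stop(sprintf(...), call. = FALSE)

# internal: evaluate code under a fixed seed without disturbing the caller's
# RNG stream (so seeded internals never couple independent loops)
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}
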