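#' Derive reproducible child seeds from a master seed
#'
#' All stochastic generators in the package draw their randomness from a
#' single integer master seed. Independent stages (genome simulation, trait
#' assignment, each trial, ...) receive child seeds produced by this splitting
#' scheme so that changing the number of draws in one stage never perturbs
#' another.
#'
#' The scheme is a multiplicative hash: child k = (seed * 48271 + k * 1299709)
#' mod (2^31 - 1), kept strictly below 2^31 so the values are valid R integer
#' seeds.
#'
#' @param seed integer master seed.
#' @param n number of child seeds required.
#' @param salt optional integer offset separating named stages that share a
#'   master seed.
#' @return integer vector of `n` child seeds.
#' @export
split_seed <- function(seed, n, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(seed) %% m)
  k <- seq_len(n) + as.double(salt)
  as.integer((s * 48271 + k * 1299709) %% m)
}

# internal: stop with a classed error so callers can distinguish validation
# failures from numerical ones
abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("caulipheno_validation_error", "error")))
}
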