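#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic component of the pipeline draws its randomness from a
#' child seed derived deterministically from a single master seed plus a
#' component label (and optionally an index). This means any component can be
#' regenerated in isolation and two runs with the same master seed are
#' identical, while different components never share an RNG stream.
#'
#' The derivation is a fixed multiplicative hash: the label is folded into an
#' integer with a base-31 polynomial hash, combined with the master seed and
#' index by a Lehmer-style step, all modulo 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param label character scalar naming the component.
#' @param index optional non-negative integer for families of seeds.
#' @return an integer in [1, 2^31 - 2], usable with [set.seed()].
#' @export
child_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.character(label), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  x <- (abs(seed) %% m)
  x <- (x * 48271 + h * 7919 + index * 104729 + 12345) %% m
  x <- (x * 48271 + 1) %% m
  as.integer(if (x == 0) 1 else x)
}
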