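#' Derive a reproducible sub-stream seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed
#' deterministically from a single master seed and a stage label, so that
#' stages are reproducible independently of execution order.  The label is
#' hashed with a 31-ary polynomial rolling hash and mixed with the master
#' seed by a Lehmer step, all modulo the Mersenne prime 2^31 - 1 (so the
#' result is always a valid 32-bit integer seed).
#'
#' @param master Integer master seed.
#' @param stage Character scalar labelling the stage or sub-stream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "design")
#' derive_seed(1, "simulate")
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage),
            length(stage) == 1L)
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  s <- (abs(master) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + h) %% m
  s <- (s * 48271) %% m
  as.integer(s %% (m - 1) + 1)
}
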