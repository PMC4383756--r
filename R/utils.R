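# Internal helpers: error raising with class, seed derivation.

stop_data <- function(fmt, ..., class = "dclineage_data_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

stop_config <- function(fmt, ...) {
  stop_data(fmt, ..., class = "dclineage_config_error")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a root seed
#'
#' All stochastic generators in the package draw from streams seeded by fixed
#' offsets from one root seed, so adding a sample or stage never perturbs the
#' draws of earlier ones. Results always fit in a 32-bit integer.
#'
#' @param seed integer root seed.
#' @param offset non-negative integer stream offset.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, offset) {
  seed <- as.integer(seed) %% 1000003L
  as.integer((seed * 2048L + as.integer(offset)) %% 2147483629L)
}
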