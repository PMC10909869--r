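#' @importFrom stats rnorm runif rbinom quantile
#' @importFrom utils head tail
NULL

# Internal: run `code` under a temporary RNG state seeded with `seed`.
# All stochastic operations in the package go through this so that every
# generator and training run is a pure function of its seed argument.
seeded <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# Internal: derive a child seed from a parent seed and a stream index,
# kept within 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9973L) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nf <- function(...) stop(sprintf(...), call. = FALSE)
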