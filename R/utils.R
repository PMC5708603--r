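#' @keywords internal
#' @import Matrix
"_PACKAGE"

# Deterministic 31-adic string hash folded into [0, 2^31 - 2].
# Doubles are exact below 2^53, so (h * 31 + byte) stays exact before
# each modulo reduction.
hash_string <- function(x) {
  h <- 0
  for (b in utf8ToInt(as.character(x))) {
    h <- (h * 31 + b) %% 2147483647
  }
  h
}

#' Derive a reproducible RNG seed from a global seed and context labels
#'
#' Combines a user-supplied global seed with an arbitrary number of
#' context labels (sample IDs, bin sizes, replicate indices) into a
#' single integer seed strictly below 2^31, so that every stochastic
#' stage of the pipeline can draw its own independent, reproducible
#' random stream.
#'
#' @param global_seed integer global seed.
#' @param ... context labels (coerced to character) that identify the
#'   stream, e.g. a sample ID and a null-bin seed size.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(global_seed, ...) {
  h <- as.numeric(global_seed) %% 2147483647
  for (part in list(...)) {
    h <- (h * 31 + hash_string(part)) %% 2147483647
  }
  as.integer(max(1, h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vlog <- function(verbose, ...) {
  if (isTRUE(verbose)) message(...)
}
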