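# Internal helpers shared across modules.

DIET_LEVELS <- c("OMN", "VGTR", "VGN")

#' Derive a named substream seed from a master seed
#'
#' One master seed is split into independent named substreams
#' (cohort / metabolome / biomarkers / permutation ...) so that adding a
#' simulation stage never perturbs the draws of an earlier stage. The
#' derivation hashes the stream name into a 31-bit integer offset.
#'
#' @param seed master seed (single integer).
#' @param stream character stream name.
#' @return an integer seed suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "cohort")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(seed) + h) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

# Validate a numeric scalar, with a name for the error message.
check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop_input("invalid configuration field '%s': must be a number in [%s, %s]",
               name, format(lo), format(hi))
  }
  invisible(x)
}
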