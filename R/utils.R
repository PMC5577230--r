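#' @keywords internal
"_PACKAGE"

#' Round half up
#'
#' Fixed-decimal rounding with ties going away from zero, as used for every
#' percentage the pipeline reports. `round()` in R rounds half to even, which
#' does not reproduce hand-computed report percentages such as 126/148 ->
#' 85.1%.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage under the shared reporting rule
#'
#' @param count numerator (count).
#' @param total denominator (count); must be > 0.
#' @return `100 * count / total` rounded half-up to one decimal.
#' @export
percent_of <- function(count, total) {
  stopifnot(total > 0)
  round_half_up(100 * count / total, 1)
}

# Counter-based seed splitting: a sub-stream seed that depends only on the
# base seed and the counter, never on how many draws earlier streams made.
# Constants are primes; result stays inside 32-bit signed range.
derive_seed <- function(seed, counter, salt = 0L) {
  ((as.double(seed) %% 2147483647) * 48271 +
    as.double(counter) * 104729 +
    as.double(salt) * 7919) %% 2147483647
}

# Run `expr` under a local RNG stream without touching the caller's RNG state.
with_local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# IUPAC nucleotide code expansions, as base-set character vectors.
iupac_sets <- function() {
  lapply(Biostrings::IUPAC_CODE_MAP, function(x) strsplit(x, "")[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)
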