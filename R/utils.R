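#' Round half away from zero
#'
#' Fixed-point rounding with ties going away from zero, as used for the
#' percentages and Mb spans in all reports (base \code{round()} rounds ties
#' to even, which would turn 3.75 into 3.8 but 3.65 into 3.6).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Derive a stage seed from a global seed
#'
#' Stable fan-out of one global seed into independent per-stage seeds so
#' pipeline stages can be rerun in isolation and still reproduce. The
#' derived seed is always a valid 32-bit R integer.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- rlang::hash(list(as.integer(seed), stage))
  strtoi(substr(h, 1L, 7L), base = 16L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
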