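#' Round half away from zero
#'
#' Rounds to the nearest integer with halves rounded up (0.5 -> 1, 2.5 -> 3),
#' unlike [base::round()]'s round-half-to-even. Used wherever effort-scaled
#' counts must be turned back into integers for exact tests.
#'
#' @param x numeric vector (assumed non-negative in this package's use).
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Derive a deterministic sub-seed from a master seed
#'
#' Keeps all stages of a pipeline run reproducible from one integer while
#' giving each stage an independent stream. The result is always a valid
#' 32-bit seed.
#'
#' @param seed master seed (integer).
#' @param stream integer stream index (>= 0).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream = 0L) {
  s <- (abs(as.double(seed)) * 48271 + as.double(stream) * 99991 + 12345) %%
    2147483646
  as.integer(s) + 1L
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_input(sprintf("'%s' must be a probability in [0, 1]", name))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop_input(sprintf("'%s' must be an integer >= %d", name, min))
  }
  invisible(x)
}

assert_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop_input(sprintf("'%s' must be a number in [%s, %s]", name, min, max))
  }
  invisible(x)
}
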