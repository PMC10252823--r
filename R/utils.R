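# Internal helpers shared across modules.

#' Derive a child seed from a root seed and a stage tag
#'
#' All stochastic stages draw their own seed from one root seed so that a
#' single integer reproduces the whole pipeline. Kept below 2^31 - 1.
#'
#' @param seed root integer seed.
#' @param tag short character tag naming the stage.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_input <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# sample standard deviation that returns 0 (not NA) for n == 1
sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
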