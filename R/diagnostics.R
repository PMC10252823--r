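# mixing_model module: MCMC convergence diagnostics.

#' Gelman-Rubin potential scale reduction factor
#'
#' \deqn{\hat R = \sqrt{\frac{W (n-1)/n + B/n}{W}}}
#' with W the mean within-chain variance and B the between-chain variance
#' of the chain means. By default each chain is split in half first
#' (split-chain PSRF), which also detects within-chain drift; `split =
#' FALSE` gives the classic unsplit form (for which identical duplicated
#' chains yield B = 0 and R-hat <= 1 exactly).
#'
#' @param chains list of >= 2 numeric vectors of equal length >= 10.
#' @param split split each chain in half before computing (default TRUE).
#' @return R-hat (NA with a warning when all chains have zero variance).
#' @export
gelman_rubin <- function(chains, split = TRUE) {
  if (!is.list(chains) || length(chains) < 2) {
    abort_input("need at least 2 chains")
  }
  len <- unique(vapply(chains, length, integer(1)))
  if (length(len) != 1 || len < 10) {
    abort_input("chains must have equal lengths >= 10")
  }
  if (split) {
    half <- floor(len / 2)
    chains <- unlist(lapply(chains, function(x) {
      list(x[seq_len(half)], x[seq.int(len - half + 1, len)])
    }), recursive = FALSE)
  }
  n <- length(chains[[1]])
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= .Machine$double.eps) {
    warning("zero within-chain variance; R-hat undefined", call. = FALSE)
    return(NA_real_)
  }
  sqrt((W * (n - 1) / n + B / n) / W)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first `first_frac` of a chain with the mean of
#' the last `last_frac`, standardized by spectral-density-at-zero standard
#' errors: z = (mean_first - mean_last) / sqrt(se1^2 + se2^2). The spectral
#' density at zero is estimated from an AR fit (order chosen by AIC),
#' falling back to a batch-means estimate when the AR fit is unavailable.
#' |z| > ~2-3 indicates the chain start has not converged to the stationary
#' distribution.
#'
#' @param chain numeric vector, length >= 100.
#' @param first_frac,last_frac segment fractions (defaults 0.1 and 0.5).
#' @return a list with `z` and `degenerate` (TRUE for a constant chain,
#'   where z is reported as 0).
#' @export
geweke <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  n <- length(chain)
  if (n < 100) abort_input("chain too short for Geweke (need >= 100)")
  a <- chain[seq_len(max(2, floor(first_frac * n)))]
  b <- chain[seq.int(n - max(2, floor(last_frac * n)) + 1, n)]
  if (stats::var(chain) <= .Machine$double.eps) {
    return(list(z = 0, degenerate = TRUE))
  }
  se2 <- function(x) {
    # spectral density at zero via AR fit (coda-style)
    s0 <- tryCatch({
      fit <- stats::ar(x, aic = TRUE, order.max = min(20L, length(x) %/% 4))
      fit$var.pred / (1 - sum(fit$ar))^2
    }, error = function(e) NA_real_)
    if (is.finite(s0)) return(s0 / length(x))
    nb <- max(2L, floor(sqrt(length(x))))
    bs <- floor(length(x) / nb)
    bm <- vapply(seq_len(nb), function(i) {
      mean(x[seq.int((i - 1) * bs + 1, i * bs)])
    }, numeric(1))
    stats::var(bm) / nb
  }
  z <- (mean(a) - mean(b)) / sqrt(se2(a) + se2(b))
  list(z = z, degenerate = FALSE)
}
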