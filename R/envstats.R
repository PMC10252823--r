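# envstats module: correlation-matrix PCA, Kruskal-Wallis, Dunn-Bonferroni,
# Pearson correlation.

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value
#' (df = groups - 1). Computed via [stats::kruskal.test()].
#'
#' @param groups list of >= 2 numeric vectors (each n >= 1, total N >= 3).
#' @return object of class `kruskal_result`: `h`, `df`, `p`,
#'   `tie_corrected`, `degenerate` (all pooled values identical; H = 0).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort_input("need >= 2 groups")
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3) abort_input("need total N >= 3")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(values) <= .Machine$double.eps) {
    return(structure(list(h = 0, df = length(groups) - 1L, p = 1,
                          tie_corrected = TRUE, degenerate = TRUE),
                     class = "kruskal_result"))
  }
  kt <- stats::kruskal.test(values, g)
  structure(list(
    h = unname(kt$statistic), df = unname(kt$parameter),
    p = kt$p.value, tie_corrected = any(duplicated(values)),
    degenerate = FALSE), class = "kruskal_result")
}

#' @export
print.kruskal_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.4g\n",
              x$h, x$df, x$p))
  invisible(x)
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise rank comparisons after Kruskal-Wallis, on the pooled ranking:
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\big(\frac{N(N+1)}{12} - \frac{\sum(\tau^3-\tau)}{12(N-1)}\big)
#'    \big(\frac{1}{n_i}+\frac{1}{n_j}\big)}}}
#' with two-sided Normal p-values Bonferroni-corrected over all
#' k(k-1)/2 pairs.
#'
#' @param groups named (or unnamed) list of >= 2 numeric vectors, each
#'   non-empty.
#' @return a data.frame with one row per pair: `group_i, group_j, z, p_raw,
#'   p_bonferroni`.
#' @export
dunn_bonferroni <- function(groups) {
  k <- length(groups)
  if (k < 2) abort_input("need >= 2 groups")
  if (any(lengths(groups) == 0)) abort_input("empty group")
  nm <- names(groups) %||% paste0("group", seq_len(k))
  if (is.null(names(groups))) names(groups) <- nm
  values <- unlist(groups, use.names = FALSE)
  N <- length(values)
  r <- rank(values)
  g <- rep(seq_len(k), lengths(groups))
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(k, 2)
  npairs <- ncol(pairs)
  z <- p_raw <- numeric(npairs)
  for (c in seq_len(npairs)) {
    i <- pairs[1, c]; j <- pairs[2, c]
    se <- sqrt(base_var * (1 / n[i] + 1 / n[j]))
    z[c] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p_raw[c] <- 2 * stats::pnorm(-abs(z[c]))
  }
  data.frame(
    group_i = nm[pairs[1, ]], group_j = nm[pairs[2, ]],
    z = z, p_raw = p_raw,
    p_bonferroni = stats::p.adjust(p_raw, method = "bonferroni"))
}

#' Correlation-matrix PCA of environmental variables
#'
#' Variables are log10(x + 1) transformed, then the correlation matrix is
#' eigen-decomposed. Loadings are unit-norm eigenvectors, each column
#' oriented so that its largest-magnitude element is positive; variance
#' explained is eigenvalue shares (%). Variables with |loading| above
#' `loading_threshold` are reported as the interpretable variables per
#' component. Constant variables are removed with a warning.
#'
#' @param env data.frame of environmental measurements; non-numeric and id
#'   columns (`area`, `season`, `site`) are ignored.
#' @param loading_threshold |loading| cut-off for `important_variables`
#'   (default 0.6).
#' @param log_transform apply log10(x + 1) first (default TRUE).
#' @param exclude character variables excluded from the transform (still
#'   included in the PCA).
#' @return object of class `pca_result`: `loadings`, `variance_explained`,
#'   `scores`, `important_variables`, `eigenvalues`.
#' @export
pca_correlation <- function(env, loading_threshold = 0.6,
                            log_transform = TRUE, exclude = character()) {
  drop_cols <- intersect(c("area", "season", "site"), names(env))
  X <- env[setdiff(names(env), drop_cols)]
  X <- X[vapply(X, is.numeric, logical(1))]
  if (nrow(X) < 3 || ncol(X) < 2) {
    abort_input("need >= 3 samples and >= 2 variables")
  }
  if (log_transform) {
    for (v in setdiff(names(X), exclude)) X[[v]] <- log10(X[[v]] + 1)
  }
  constant <- vapply(X, function(x) stats::var(x) <= .Machine$double.eps,
                     logical(1))
  if (any(constant)) {
    warning("removing constant variable(s): ",
            paste(names(X)[constant], collapse = ", "), call. = FALSE)
    X <- X[!constant]
  }
  Xs <- scale(as.matrix(X))
  R <- stats::cor(as.matrix(X))
  eig <- eigen(R, symmetric = TRUE)
  load <- eig$vectors
  # orient each component so its largest-magnitude loading is positive
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(X), paste0("PC", seq_len(ncol(load))))
  ve <- 100 * eig$values / sum(eig$values)
  scores <- Xs %*% load
  important <- apply(load, 2, function(l) {
    rownames(load)[abs(l) > loading_threshold]
  }, simplify = FALSE)
  structure(list(
    loadings = load, variance_explained = ve, scores = scores,
    important_variables = important, eigenvalues = eig$values),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("PC1 %.2f%%, PC2 %.2f%% (first two axes: %.2f%%)\n",
              ve[1], ve[2], ve[1] + ve[2]))
  invisible(x)
}

#' Pearson correlation with two-sided t-test
#'
#' Sample Pearson r with the usual two-sided p from
#' t = r sqrt((n-2)/(1-r^2)); used for seston-vs-phytoplankton source
#' screening. Computed via [stats::cor.test()].
#'
#' @param x,y paired numeric vectors, n >= 3, non-zero variances.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort_input("need >= 3 paired values")
  }
  if (stats::var(x) <= 0 || stats::var(y) <= 0) {
    abort_input("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
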