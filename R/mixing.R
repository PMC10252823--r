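# mixing_model module: Bayesian inference of dietary source proportions.

#' Fit a Bayesian source-mixing model for one consumer group
#'
#' Models each consumer's corrected isotope values as a proportion-weighted
#' mixture of source signatures. For consumer j and isotope X:
#' \deqn{\delta_{jX} \sim N\big(\sum_k p_k(\mu_{kX}+\lambda_X),\;
#'   \sum_k p_k^2(\sigma_{kX}^2+\tau_X^2) + \epsilon_X^2\big)}
#' with \eqn{\lambda} the model discrimination means (default 0),
#' \eqn{\tau} its SDs (default 1.3 per-mil C, 1.0 per-mil N), and
#' \eqn{\epsilon_X} residual SDs with half-Normal(0, 5) priors. The diet
#' vector p has a flat Dirichlet(1, ..., 1) prior and is sampled on
#' unconstrained log-ratio coordinates by adaptive random-walk Metropolis
#' (Haario-style covariance adaptation during burn-in, acceptance targeted
#' to 20-40%). Post-burn-in draws are thinned and pooled across chains.
#'
#' @param consumers data.frame of corrected samples for one group
#'   (`d13c_corr`/`d15n_corr`, falling back to `d13c`/`d15n`); >= 2 rows.
#' @param sources per-source summary (`source, mu13, sd13, mu15, sd15`),
#'   one row per source, K >= 1.
#' @param model_tdf list with `mean` and `sd`, each length 2 (C, N), the
#'   discrimination distribution assumed by the model.
#' @param settings MCMC settings list (`chains, iterations, burn_in, thin`),
#'   e.g. [mcmc_desk_profile()] or `default_config()$mcmc`.
#' @param residual_prior_sd scale of the half-Normal prior on the residual
#'   SDs (per-mil).
#' @param credibility central credible-interval mass (default 0.95).
#' @param seed integer seed; chains use derived sub-seeds.
#' @param group optional identifier (e.g. list(area, season, taxon_group))
#'   carried into the result.
#' @param prior_only if TRUE the likelihood is disabled and the sampler
#'   targets the prior (for calibration checks).
#' @return an object of class `mixing_result`: pooled `draws` (matrix,
#'   one column per source, each row on the simplex), `medians`, `ci95`,
#'   per-source `rhat` and `geweke_z`, residual-SD draws (`eps_draws`),
#'   `n_consumers`, `converged`.
#' @export
fit_mixing_model <- function(consumers, sources,
                             model_tdf = list(mean = c(0, 0),
                                              sd = c(1.3, 1.0)),
                             settings = mcmc_desk_profile(),
                             residual_prior_sd = 5,
                             credibility = 0.95,
                             seed = 1L, group = NULL, prior_only = FALSE) {
  K <- nrow(sources)
  src_names <- sources$source
  y1 <- consumers[["d13c_corr"]] %||% consumers[["d13c"]]
  y2 <- consumers[["d15n_corr"]] %||% consumers[["d15n"]]
  if (K == 1L) {
    draws <- matrix(1, nrow = 1000, ncol = 1,
                    dimnames = list(NULL, src_names))
    return(structure(list(
      group = group, sources = src_names, draws = draws,
      medians = stats::setNames(1, src_names),
      ci95 = matrix(c(1, 1), 2, 1, dimnames = list(c("lower", "upper"),
                                                   src_names)),
      rhat = stats::setNames(NA_real_, src_names),
      geweke_z = stats::setNames(NA_real_, src_names),
      eps_draws = NULL, n_consumers = length(y1), converged = TRUE,
      settings = settings), class = "mixing_result"))
  }
  if (!prior_only && length(y1) < 2) {
    abort_input("insufficient data: need >= 2 consumers")
  }
  if (anyNA(sources$sd13) || anyNA(sources$sd15)) {
    abort_input("sources with undefined SD cannot enter the model")
  }
  stopifnot(settings$burn_in < settings$iterations, settings$thin >= 1,
            settings$chains >= 2)
  n_keep <- floor((settings$iterations - settings$burn_in) / settings$thin)
  if (n_keep < 500) {
    warning("fewer than 500 retained draws per chain", call. = FALSE)
  }

  mu1 <- sources$mu13 + model_tdf$mean[[1]]
  mu2 <- sources$mu15 + model_tdf$mean[[2]]
  v1 <- sources$sd13^2 + model_tdf$sd[[1]]^2
  v2 <- sources$sd15^2 + model_tdf$sd[[2]]^2
  two_s2 <- 2 * residual_prior_sd^2
  D <- K + 1L  # K-1 log-ratio coords + 2 log residual SDs

  log_post <- function(theta) {
    z <- c(theta[seq_len(K - 1)], 0)
    z <- z - max(z)
    ez <- exp(z)
    p <- ez / sum(ez)
    if (any(p <= 0)) return(-Inf)
    lp <- sum(log(p))  # Dirichlet(1) x log-ratio Jacobian
    u <- theta[K:(K + 1)]
    e2 <- exp(2 * u)
    lp <- lp + sum(-e2 / two_s2 + u)  # half-Normal prior + Jacobian
    if (!prior_only) {
      m1 <- sum(p * mu1); s1 <- sqrt(sum(p^2 * v1) + e2[1])
      m2 <- sum(p * mu2); s2 <- sqrt(sum(p^2 * v2) + e2[2])
      lp <- lp + sum(stats::dnorm(y1, m1, s1, log = TRUE)) +
        sum(stats::dnorm(y2, m2, s2, log = TRUE))
    }
    lp
  }

  to_p <- function(theta_mat) {
    z <- cbind(theta_mat[, seq_len(K - 1), drop = FALSE], 0)
    ez <- exp(z - apply(z, 1, max))
    ez / rowSums(ez)
  }

  chain_p <- vector("list", settings$chains)
  chain_eps <- vector("list", settings$chains)
  for (ch in seq_len(settings$chains)) {
    set.seed(derive_seed(seed, paste0("mix-chain-", ch)))
    theta <- c(stats::rnorm(K - 1, 0, 1), stats::rnorm(2, 0, 0.5))
    res <- run_amrw_chain(log_post, theta, settings, D)
    chain_p[[ch]] <- to_p(res$draws)
    chain_eps[[ch]] <- exp(res$draws[, K:(K + 1), drop = FALSE])
  }

  rhat <- vapply(seq_len(K), function(k) {
    gelman_rubin(lapply(chain_p, function(m) m[, k]))
  }, numeric(1))
  gz <- vapply(seq_len(K), function(k) geweke(chain_p[[1]][, k])$z,
               numeric(1))
  names(rhat) <- names(gz) <- src_names

  draws <- do.call(rbind, chain_p)
  colnames(draws) <- src_names
  summ <- summarize_posterior(draws, credibility = credibility)
  converged <- all(is.na(rhat) | rhat < 1.1)
  if (!converged) {
    warning("non-convergence: max Rhat = ", round(max(rhat, na.rm = TRUE), 3),
            call. = FALSE)
  }
  structure(list(
    group = group, sources = src_names, draws = draws,
    medians = summ$medians, ci95 = summ$intervals,
    rhat = rhat, geweke_z = gz,
    eps_draws = do.call(rbind, chain_eps),
    n_consumers = length(y1), converged = converged,
    settings = settings), class = "mixing_result")
}

# Adaptive random-walk Metropolis. Scale adaptation every 50 iterations and
# Haario covariance adaptation (running moments) during burn-in only; the
# kernel is frozen afterwards so the retained draws target the posterior.
run_amrw_chain <- function(log_post, theta, settings, D) {
  n_iter <- settings$iterations
  burn <- settings$burn_in
  thin <- settings$thin
  n_keep <- floor((n_iter - burn) / thin)
  draws <- matrix(NA_real_, n_keep, D)
  lp <- log_post(theta)
  if (!is.finite(lp)) {
    theta <- rep(0, D)
    lp <- log_post(theta)
  }
  log_scale <- log(2.38 / sqrt(D))
  L <- diag(D)  # chol factor of proposal covariance
  mean_acc <- 0; window <- 0L
  m <- rep(0, D); M2 <- matrix(0, D, D); n_mom <- 0L
  kept <- 0L
  for (it in seq_len(n_iter)) {
    prop <- theta + exp(log_scale) * as.numeric(L %*% stats::rnorm(D))
    lp_prop <- log_post(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      theta <- prop; lp <- lp_prop
      mean_acc <- mean_acc + 1
    }
    window <- window + 1L
    if (it <= burn) {
      n_mom <- n_mom + 1L
      d <- theta - m
      m <- m + d / n_mom
      M2 <- M2 + tcrossprod(d, theta - m)
      if (window == 50L) {
        log_scale <- log_scale + 0.5 * (mean_acc / 50 - 0.3)
        mean_acc <- 0; window <- 0L
        if (it >= 1000L && n_mom > 2L) {
          S <- M2 / (n_mom - 1) + diag(1e-6, D)
          ch <- tryCatch(chol(S), error = function(e) NULL)
          if (!is.null(ch)) L <- t(ch)
        }
      }
    } else if (window == 50L) {
      mean_acc <- 0; window <- 0L
    }
    if (it > burn && (it - burn) %% thin == 0L && kept < n_keep) {
      kept <- kept + 1L
      draws[kept, ] <- theta
    }
  }
  list(draws = draws)
}

#' Summarize posterior diet draws
#'
#' Per-source posterior median and central credible interval.
#'
#' @param draws matrix of posterior draws (rows) by source (columns).
#' @param credibility central interval mass (default 0.95).
#' @return list with `medians` (named vector), `intervals` (2 x K matrix,
#'   rows lower/upper) and `table` (a report view with percentages rounded
#'   to integers alongside the raw values).
#' @export
summarize_posterior <- function(draws, credibility = 0.95) {
  draws <- as.matrix(draws)
  a <- (1 - credibility) / 2
  medians <- apply(draws, 2, stats::median)
  intervals <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a),
                     names = FALSE)
  rownames(intervals) <- c("lower", "upper")
  tab <- data.frame(
    source = colnames(draws) %||% paste0("p", seq_len(ncol(draws))),
    median = medians, lower = intervals[1, ], upper = intervals[2, ],
    pct = round(100 * medians),
    pct_lower = round(100 * intervals[1, ]),
    pct_upper = round(100 * intervals[2, ]),
    row.names = NULL)
  list(medians = medians, intervals = intervals, table = tab)
}

#' @export
print.mixing_result <- function(x, ...) {
  if (!is.null(x$group)) {
    cat("Group:", paste(unlist(x$group), collapse = " / "), "\n")
  }
  s <- summarize_posterior(x$draws)
  tab <- s$table
  tab$rhat <- round(x$rhat[tab$source], 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
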