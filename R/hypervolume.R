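# niche_hypervolume module: dietary-niche hypervolumes from posterior diet
# proportions and Sorensen overlap between communities.

#' Assemble dietary niche points for one area
#'
#' One point per mixing result (i.e. per taxon group x season): the vector
#' of posterior median diet proportions over the retained sources. The
#' dimensions of the niche space are the source names, in the order of the
#' first result.
#'
#' @param results list of `mixing_result` objects for one area (>= 2).
#' @param area optional area label recorded on the output (taken from the
#'   first result's group when absent).
#' @return object of class `niche_point_set`: list with `area`, `points`
#'   (matrix, rows = results, columns = sources).
#' @export
assemble_niche_points <- function(results, area = NULL) {
  if (length(results) < 2) {
    abort_input("insufficient data: need >= 2 mixing results per area")
  }
  src <- results[[1]]$sources
  pts <- t(vapply(results, function(r) {
    if (!identical(r$sources, src)) {
      abort_input("dimension mismatch: inconsistent source sets across results")
    }
    unname(r$medians)
  }, numeric(length(src))))
  colnames(pts) <- src
  rownames(pts) <- vapply(results, function(r) {
    g <- r$group
    if (is.null(g)) "" else paste(unlist(g), collapse = "_")
  }, character(1))
  degenerate <- all(apply(pts, 2, function(x) diff(range(x)) < 1e-12))
  if (degenerate) {
    warning("degenerate niche cloud: all points identical", call. = FALSE)
  }
  area <- area %||% (results[[1]]$group$area %||% NA_character_)
  structure(list(area = area, points = pts, degenerate = degenerate),
            class = "niche_point_set")
}

#' Pooled z-standardization of niche point sets
#'
#' Standardizes every dimension by the mean and sample SD pooled across all
#' areas' points, so that volumes are comparable between communities.
#' Zero-variance dimensions are dropped with a warning.
#'
#' @param point_sets list of `niche_point_set` objects (or plain matrices)
#'   sharing identical dimension names.
#' @return list with `sets` (the standardized point sets) and `z_params`
#'   (per-dimension mean and SD used).
#' @export
z_transform <- function(point_sets) {
  mats <- lapply(point_sets, function(s) {
    if (inherits(s, "niche_point_set")) s$points else as.matrix(s)
  })
  pooled <- do.call(rbind, mats)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warning("dropping zero-variance dimension(s): ",
            paste(colnames(pooled)[!keep], collapse = ", "), call. = FALSE)
  }
  sets <- lapply(seq_along(mats), function(i) {
    m <- sweep(sweep(mats[[i]][, keep, drop = FALSE], 2, mu[keep]), 2,
               sdv[keep], "/")
    if (inherits(point_sets[[i]], "niche_point_set")) {
      out <- point_sets[[i]]
      out$points <- m
      out$z_params <- list(mean = mu[keep], sd = sdv[keep])
      out
    } else m
  })
  names(sets) <- names(point_sets)
  list(sets = sets, z_params = list(mean = mu[keep], sd = sdv[keep]))
}

# Gaussian product-kernel density of `x` (m x d) under KDE of `data`
# (n x d) with per-dimension bandwidths h. Chunked over query rows.
kde_density <- function(x, data, h) {
  x <- rbind(x)
  n <- nrow(data); m <- nrow(x); d <- ncol(data)
  out <- numeric(m)
  chunk <- max(1L, floor(2e6 / n))
  start <- 1L
  while (start <= m) {
    end <- min(m, start + chunk - 1L)
    idx <- start:end
    logk <- matrix(0, length(idx), n)
    for (j in seq_len(d)) {
      z <- outer(x[idx, j], data[, j], "-") / h[j]
      logk <- logk - 0.5 * z^2
    }
    lc <- -sum(log(h)) - d / 2 * log(2 * pi) - log(n)
    out[idx] <- rowSums(exp(logk + lc))
    start <- end + 1L
  }
  out
}

#' Build a Gaussian kernel-density hypervolume
#'
#' Characterizes the region of niche space holding `mass_quantile` of the
#' probability mass of a Gaussian product-kernel KDE of the (standardized)
#' points. Per-dimension Silverman bandwidths
#' h_i = sd_i (4 / ((d + 2) n))^(1/(d+4)) are used; `n_mc` points are
#' sampled from the KDE mixture; the density threshold c is the sample
#' quantile such that a `mass_quantile` fraction of sampled points have
#' density >= c; the volume is the importance-sampling estimate
#' V = (1/M) sum over retained samples of 1/f(x). A quasi-uniform point
#' cloud inside the region (importance resampling with weights 1/f) is
#' retained for overlap computations.
#'
#' @param points standardized point matrix (n >= 2 distinct rows, d <= 6).
#' @param mass_quantile enclosed probability mass (default 0.95).
#' @param point_density target cloud points per unit volume (cloud size is
#'   `point_density * volume`, clamped to \[200, 5000\]).
#' @param n_mc Monte Carlo samples from the KDE (default 10000).
#' @param seed integer seed.
#' @return object of class `hypervolume`: `volume` (z-units^d), `cloud`,
#'   `bandwidth`, `density_threshold`, `data`, `mass_quantile`.
#' @export
build_hypervolume <- function(points, mass_quantile = 0.95,
                              point_density = 100, n_mc = 10000L,
                              seed = 1L) {
  data <- as.matrix(points)
  n <- nrow(data); d <- ncol(data)
  if (nrow(unique(data)) < 2) {
    abort_input("degenerate data: need >= 2 distinct points")
  }
  if (d > 6) abort_input("dimension too high (d <= 6 supported)")
  sdv <- apply(data, 2, stats::sd)
  if (any(sdv <= 0)) {
    abort_input("degenerate data: zero-variance dimension; z-transform and ",
                "drop constant dimensions first")
  }
  h <- sdv * (4 / ((d + 2) * n))^(1 / (d + 4))
  set.seed(seed)
  idx <- sample.int(n, n_mc, replace = TRUE)
  x <- data[idx, , drop = FALSE] +
    matrix(stats::rnorm(n_mc * d), n_mc, d) %*% diag(h, d)
  f <- kde_density(x, data, h)
  thr <- stats::quantile(f, 1 - mass_quantile, names = FALSE)
  keep <- f >= thr
  volume <- sum(1 / f[keep]) / n_mc
  n_cloud <- min(5000L, max(200L, round(point_density * volume)))
  w <- 1 / f[keep]
  cloud_idx <- sample(which(keep), n_cloud, replace = TRUE, prob = w)
  structure(list(
    data = data, bandwidth = h, density_threshold = thr,
    volume = volume, cloud = x[cloud_idx, , drop = FALSE],
    mass_quantile = mass_quantile, n_mc = as.integer(n_mc),
    dim = d), class = "hypervolume")
}

#' Test membership of points in a hypervolume
#'
#' @param hv a `hypervolume`.
#' @param x points (matrix m x d).
#' @return logical vector: KDE density at x >= the stored threshold.
#' @export
hypervolume_contains <- function(hv, x) {
  kde_density(x, hv$data, hv$bandwidth) >= hv$density_threshold
}

#' Sorensen overlap of two hypervolumes
#'
#' Intersection volume is estimated by cross-membership of the two uniform
#' clouds (fraction of each cloud inside the other region, times the
#' respective volume, averaged) and capped at min(V1, V2); Sorensen
#' similarity is 2 V_int / (V1 + V2). The 95% CI comes from bootstrap
#' resampling of the underlying niche points with both hypervolumes rebuilt
#' per replicate (percentile interval).
#'
#' @param h1,h2 `hypervolume` objects built in the same standardized space.
#' @param bootstrap_reps bootstrap replicates (default 100; 0 skips the CI).
#' @param n_mc_boot Monte Carlo samples per bootstrap rebuild.
#' @param seed integer seed.
#' @return object of class `overlap_result`: `sorensen`, `v1`, `v2`,
#'   `v_intersection`, `ci95`, `bootstrap_reps`.
#' @export
sorensen_overlap <- function(h1, h2, bootstrap_reps = 100L,
                             n_mc_boot = 2000L, seed = 1L) {
  if (h1$dim != h2$dim ||
      !identical(colnames(h1$data), colnames(h2$data))) {
    abort_input("dimension mismatch between hypervolumes")
  }
  point_sorensen <- function(a, b) {
    f12 <- mean(hypervolume_contains(b, a$cloud))
    f21 <- mean(hypervolume_contains(a, b$cloud))
    v_int <- min((f12 * a$volume + f21 * b$volume) / 2,
                 a$volume, b$volume)
    list(s = 2 * v_int / (a$volume + b$volume), v_int = v_int)
  }
  est <- point_sorensen(h1, h2)
  ci <- c(NA_real_, NA_real_)
  if (bootstrap_reps > 0) {
    reps <- numeric(bootstrap_reps)
    for (r in seq_len(bootstrap_reps)) {
      s1 <- derive_seed(seed, paste0("boot1-", r))
      s2 <- derive_seed(seed, paste0("boot2-", r))
      set.seed(derive_seed(seed, paste0("boot-idx-", r)))
      i1 <- sample.int(nrow(h1$data), replace = TRUE)
      i2 <- sample.int(nrow(h2$data), replace = TRUE)
      b1 <- try_build(h1$data[i1, , drop = FALSE], h1$mass_quantile,
                      n_mc_boot, s1)
      b2 <- try_build(h2$data[i2, , drop = FALSE], h2$mass_quantile,
                      n_mc_boot, s2)
      reps[r] <- if (is.null(b1) || is.null(b2)) NA_real_ else
        point_sorensen(b1, b2)$s
    }
    reps <- reps[is.finite(reps)]
    if (length(reps) >= 10) {
      ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
      ci <- pmin(pmax(ci, 0), 1)
    }
  }
  structure(list(
    sorensen = est$s, v1 = h1$volume, v2 = h2$volume,
    v_intersection = est$v_int, ci95 = ci,
    bootstrap_reps = as.integer(bootstrap_reps)), class = "overlap_result")
}

# bootstrap resamples can be degenerate (all rows identical); skip those
try_build <- function(points, mass_quantile, n_mc, seed) {
  tryCatch(
    build_hypervolume(points, mass_quantile = mass_quantile, n_mc = n_mc,
                      seed = seed),
    error = function(e) NULL)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Sorensen = %.3f (95%% CI %.3f-%.3f)\n", x$sorensen,
              x$ci95[1], x$ci95[2]))
  cat(sprintf("V1 = %.2f, V2 = %.2f, V_intersection = %.2f\n",
              x$v1, x$v2, x$v_intersection))
  invisible(x)
}
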