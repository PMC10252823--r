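# preprocess module: delta computation, lipid normalization, trophic
# correction, source screening, source summaries, mixing-polygon check.

#' Delta notation
#'
#' Converts an isotope ratio to delta notation relative to a standard:
#' deltaX = (R_sample / R_standard - 1) x 1000, in per-mil. Provided for
#' completeness and testing; field delta values are assumed already
#' calibrated.
#'
#' @param r_sample,r_standard isotope ratios (e.g. 13C/12C); must be > 0.
#' @return delta value(s) in per-mil.
#' @export
#' @examples
#' compute_delta(1.01, 1)  # 10 per-mil
compute_delta <- function(r_sample, r_standard) {
  if (any(r_sample <= 0) || any(r_standard <= 0)) {
    abort_input("domain error: isotope ratios must be positive")
  }
  (r_sample / r_standard - 1) * 1000
}

#' Lipid normalization of d13C
#'
#' Arithmetic lipid correction for aquatic animal tissue:
#' d13C_norm = d13C - 3.32 + 0.99 x C:N, applied only when the C:N ratio
#' exceeds `threshold` (default 3.5, below which tissue is considered
#' lipid-lean). Missing C:N leaves the value unchanged with a warning.
#'
#' @param d13c d13C values (per-mil).
#' @param c_to_n C:N ratios (may contain NA).
#' @param threshold C:N value at or below which no correction is applied.
#' @return normalized d13C values, with attribute `"applied"` a logical
#'   vector marking the rows that were corrected.
#' @export
lipid_normalize <- function(d13c, c_to_n, threshold = 3.5) {
  c_to_n <- rep_len(c_to_n, length(d13c))
  if (any(!is.na(c_to_n) & c_to_n <= 0)) {
    abort_input("domain error: C:N ratio must be positive")
  }
  if (anyNA(c_to_n)) {
    warning("C:N missing for ", sum(is.na(c_to_n)),
            " sample(s); d13c left unchanged", call. = FALSE)
  }
  apply_it <- !is.na(c_to_n) & c_to_n > threshold
  out <- ifelse(apply_it, d13c - 3.32 + 0.99 * c_to_n, d13c)
  attr(out, "applied") <- apply_it
  out
}

#' Trophic-discrimination correction
#'
#' De-enriches consumer isotope values to basal-resource (trophic level 1)
#' space: d13c_corr = d13c - (TL - 1) * Delta13C and likewise for d15n.
#' This matches a mixing model parameterized with zero-mean discrimination.
#'
#' @param samples consumer data.frame with `d13c`, `d15n` and (unless `tl`
#'   is given) a `guild` column.
#' @param trophic_levels named numeric map guild -> trophic level.
#' @param tdf_per_level numeric length-2 `(Delta13C, Delta15N)` per trophic
#'   level, per-mil (default `c(0.4, 3.4)`).
#' @param tl optional numeric trophic level(s) overriding the guild lookup.
#' @param base_tl trophic level consumers are corrected down to (default 1,
#'   the basal level; set 2 to only remove enrichment above primary
#'   consumers).
#' @return the input with added `d13c_corr`, `d15n_corr` and
#'   `corrections_applied` columns.
#' @export
trophic_correct <- function(samples, trophic_levels = NULL,
                            tdf_per_level = c(0.4, 3.4), tl = NULL,
                            base_tl = 1) {
  if (is.null(tl)) {
    if (is.null(trophic_levels) || !"guild" %in% names(samples)) {
      abort_input("mapping error: need either tl or trophic_levels + guild")
    }
    unknown <- setdiff(unique(samples$guild), names(trophic_levels))
    if (length(unknown)) {
      taxa <- if ("taxon" %in% names(samples)) {
        paste(unique(samples$taxon[samples$guild %in% unknown]),
              collapse = ", ")
      } else "unknown taxa"
      abort_input("mapping error: no trophic level for guild(s) ",
                  paste(unknown, collapse = ", "), " (taxa: ", taxa, ")")
    }
    tl <- unname(trophic_levels[samples$guild])
  }
  if (any(tl < 1)) abort_input("domain error: trophic level must be >= 1")
  lev <- pmax(tl - base_tl, 0)
  samples$d13c_corr <- samples$d13c - lev * tdf_per_level[[1]]
  samples$d15n_corr <- samples$d15n - lev * tdf_per_level[[2]]
  samples$corrections_applied <- sprintf("trophic(tl=%g)", tl)
  samples
}

#' Screen basal sources for redundancy
#'
#' Computes Pearson correlations between paired source series on both
#' isotopes. Any pair with |r| >= `threshold` and p < `alpha` on either
#' isotope flags one member for removal: the configured lower-priority one
#' (later in `priority`), else the member with fewer observations, ties
#' broken by dropping the alphabetically later name. Pairing is by the
#' `pairing` key plus within-cell sample order. By default only positive
#' correlations flag a pair: redundancy means two series proxy the same
#' signal and co-vary; sources anti-correlated through shared seasonal
#' structure are distinct end-members, not proxies. Set `direction =
#' "both"` to flag on |r|.
#'
#' @param sources source sample data.frame (`source, area, season, d13c,
#'   d15n`).
#' @param alpha significance level (default 0.05).
#' @param threshold absolute correlation flagging threshold (default 0.6).
#' @param pairing character keys defining paired observations
#'   (default `c("area", "season")`).
#' @param priority optional character vector of source names ordered from
#'   most to least worth keeping.
#' @param direction flag pairs on positive correlation only (default) or
#'   on absolute correlation (`"both"`).
#' @return a list with `retained`, `dropped`, `r` (list of per-isotope
#'   correlation matrices) and `audit` (a data.frame trail of flagged pairs
#'   and actions).
#' @export
screen_sources <- function(sources, alpha = 0.05, threshold = 0.6,
                           pairing = c("area", "season"), priority = NULL,
                           direction = c("positive", "both")) {
  direction <- match.arg(direction)
  src_names <- sort(unique(sources$source))
  if (length(src_names) < 2) {
    abort_input("pairing error: need at least 2 sources to screen")
  }
  miss <- setdiff(pairing, names(sources))
  if (length(miss)) {
    abort_input("pairing error: pairing key(s) absent: ",
                paste(miss, collapse = ", "))
  }
  cell <- interaction(sources[pairing], drop = TRUE)
  ord <- stats::ave(seq_len(nrow(sources)),
                    interaction(cell, sources$source, drop = TRUE),
                    FUN = seq_along)
  key <- paste(as.character(cell), ord, sep = "#")

  series <- function(s, col) {
    v <- sources[[col]][sources$source == s]
    stats::setNames(v, key[sources$source == s])
  }
  K <- length(src_names)
  r13 <- r15 <- matrix(NA_real_, K, K, dimnames = list(src_names, src_names))
  diag(r13) <- diag(r15) <- 1
  audit <- data.frame(source_a = character(), source_b = character(),
                      isotope = character(), r = numeric(), p = numeric(),
                      dropped = character())
  retained <- src_names
  n_obs <- table(sources$source)

  pick_drop <- function(a, b) {
    if (!is.null(priority)) {
      ia <- match(a, priority); ib <- match(b, priority)
      if (!is.na(ia) || !is.na(ib)) {
        if (is.na(ia)) return(a)
        if (is.na(ib)) return(b)
        return(if (ia < ib) b else a)
      }
    }
    if (n_obs[[a]] != n_obs[[b]]) {
      return(if (n_obs[[a]] < n_obs[[b]]) a else b)
    }
    max(a, b)  # alphabetical tie-break: drop the later name
  }

  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      a <- src_names[i]; b <- src_names[j]
      flagged <- FALSE
      for (col in c("d13c", "d15n")) {
        xa <- series(a, col); xb <- series(b, col)
        common <- intersect(names(xa), names(xb))
        if (length(common) < 3) next
        ct <- stats::cor.test(xa[common], xb[common])
        r <- unname(ct$estimate)
        if (col == "d13c") r13[a, b] <- r13[b, a] <- r else
          r15[a, b] <- r15[b, a] <- r
        hit <- if (direction == "positive") r >= threshold else
          abs(r) >= threshold
        if (hit && ct$p.value < alpha) {
          flagged <- TRUE
          audit <- rbind(audit, data.frame(
            source_a = a, source_b = b, isotope = col,
            r = r, p = ct$p.value, dropped = ""))
        }
      }
      if (flagged && a %in% retained && b %in% retained) {
        drop <- pick_drop(a, b)
        retained <- setdiff(retained, drop)
        audit$dropped[audit$source_a == a & audit$source_b == b] <- drop
      }
    }
  }
  list(retained = retained, dropped = setdiff(src_names, retained),
       r = list(d13c = r13, d15n = r15), audit = audit)
}

#' Summarize sources for the mixing model
#'
#' Mean and sample SD (n-1 denominator) of each isotope per group (default
#' source x season). Groups with a single replicate are flagged incomplete
#' (SD missing) with a warning. Literature-supplied sources can be appended
#' with their given means/SDs.
#'
#' @param sources source sample data.frame.
#' @param group_by grouping keys (default `c("source", "season")`).
#' @param literature optional data.frame with columns `source, mu13, sd13,
#'   mu15, sd15, n` and optionally `season`; rows without a season are
#'   replicated across the seasons present in `sources`.
#' @return a data.frame of per-group summaries with columns `source,
#'   (group keys), mu13, sd13, mu15, sd15, n, flagged`.
#' @export
summarize_sources <- function(sources, group_by = c("source", "season"),
                              literature = NULL) {
  g <- interaction(sources[group_by], drop = TRUE, sep = "\r")
  split_idx <- split(seq_len(nrow(sources)), g)
  rows <- lapply(split_idx, function(idx) {
    out <- sources[idx[1], group_by, drop = FALSE]
    out$mu13 <- mean(sources$d13c[idx])
    out$sd13 <- if (length(idx) >= 2) stats::sd(sources$d13c[idx]) else NA_real_
    out$mu15 <- mean(sources$d15n[idx])
    out$sd15 <- if (length(idx) >= 2) stats::sd(sources$d15n[idx]) else NA_real_
    out$n <- length(idx)
    out$flagged <- length(idx) < 2
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$flagged)) {
    warning("source group(s) with a single replicate flagged; SD undefined",
            call. = FALSE)
  }
  if (!is.null(literature)) {
    lit <- literature
    if (!"season" %in% names(lit) && "season" %in% group_by) {
      seasons <- unique(sources$season)
      lit <- do.call(rbind, lapply(seasons, function(s) {
        x <- literature; x$season <- s; x
      }))
    }
    lit$flagged <- FALSE
    keep <- intersect(names(out), names(lit))
    out <- rbind(out[keep], lit[keep])
    rownames(out) <- NULL
  }
  out
}

#' Point-in-convex-hull test
#'
#' Half-plane membership test against an ordered convex polygon; boundary
#' points count as inside (tolerance 1e-9). Degenerate hulls (1-2 vertices)
#' reduce to point/segment proximity tests.
#'
#' @param points numeric matrix (m x 2) of query points.
#' @param hull numeric matrix of hull vertices in counter-clockwise order
#'   (as returned by [convex_hull()]).
#' @param tol boundary tolerance.
#' @return logical vector of length m.
#' @export
point_in_hull <- function(points, hull, tol = 1e-9) {
  points <- rbind(points)
  h <- nrow(hull)
  if (h == 1L) {
    return(abs(points[, 1] - hull[1, 1]) <= tol &
             abs(points[, 2] - hull[1, 2]) <= tol)
  }
  if (h == 2L) {
    a <- hull[1, ]; b <- hull[2, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((points[, 1] - a[1]) * ab[1] + (points[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- points[, 1] - (a[1] + t * ab[1])
    dy <- points[, 2] - (a[2] + t * ab[2])
    return(dx^2 + dy^2 <= tol^2)
  }
  inside <- rep(TRUE, nrow(points))
  for (i in seq_len(h)) {
    a <- hull[i, ]
    b <- hull[if (i == h) 1L else i + 1L, ]
    cross <- (b[1] - a[1]) * (points[, 2] - a[2]) -
      (b[2] - a[2]) * (points[, 1] - a[1])
    inside <- inside & (cross >= -tol)
  }
  inside
}

#' Mixing-polygon feasibility check
#'
#' Monte Carlo check that each (corrected) consumer can be explained by the
#' source set: on each iteration every source's (d13c, d15n) is drawn from
#' Normal(mean, SD), the convex hull of the draws is formed, and each
#' consumer is tested for membership. The returned inside-probability is the
#' fraction of iterations in which the consumer fell inside the polygon;
#' consumers below `threshold` are flagged for exclusion.
#'
#' @param consumers data.frame with `d13c_corr`/`d15n_corr` (or `d13c`/
#'   `d15n`) columns.
#' @param sources per-source summary rows (`source, mu13, sd13, mu15, sd15`),
#'   one row per source; at least 3 sources.
#' @param n_iter Monte Carlo iterations (>= 100).
#' @param threshold flagging probability (default 0.05).
#' @param seed integer seed.
#' @return a data.frame with one row per consumer: `inside_prob`, `flagged`,
#'   plus `sample_id` when present.
#' @export
mixing_polygon_check <- function(consumers, sources, n_iter = 1000,
                                 threshold = 0.05, seed = 1L) {
  if (nrow(sources) < 3) {
    abort_input("geometry error: mixing polygon needs at least 3 sources")
  }
  if (n_iter < 100) abort_input("n_iter must be >= 100")
  x <- consumers[["d13c_corr"]] %||% consumers[["d13c"]]
  y <- consumers[["d15n_corr"]] %||% consumers[["d15n"]]
  pts <- cbind(x, y)
  sd13 <- ifelse(is.na(sources$sd13), 0, sources$sd13)
  sd15 <- ifelse(is.na(sources$sd15), 0, sources$sd15)
  set.seed(seed)
  hits <- numeric(nrow(pts))
  for (it in seq_len(n_iter)) {
    sx <- stats::rnorm(nrow(sources), sources$mu13, sd13)
    sy <- stats::rnorm(nrow(sources), sources$mu15, sd15)
    hull <- convex_hull(cbind(sx, sy))
    hits <- hits + point_in_hull(pts, hull)
  }
  prob <- hits / n_iter
  out <- data.frame(inside_prob = prob, flagged = prob < threshold)
  if ("sample_id" %in% names(consumers)) {
    out <- cbind(sample_id = consumers$sample_id, out)
  }
  out
}
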