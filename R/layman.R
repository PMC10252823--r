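# community_metrics module (part 1): convex hull and Layman metrics.

#' Convex hull of 2-D points
#'
#' Andrew's monotone-chain algorithm. Returns the hull vertices in
#' counter-clockwise order; collinear boundary points are excluded.
#'
#' @param points numeric matrix or data.frame with 2 columns.
#' @return a numeric matrix of hull vertices (CCW). For fewer than 3
#'   distinct points the distinct points themselves are returned.
#' @export
convex_hull <- function(points) {
  p <- unique(as.matrix(points)[, 1:2, drop = FALSE])
  n <- nrow(p)
  if (n <= 2L) return(p)
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    st <- integer(0)
    for (i in idx) {
      while (length(st) >= 2 &&
             cross(p[st[length(st) - 1], ], p[st[length(st)], ], p[i, ]) <= 0) {
        st <- st[-length(st)]
      }
      st <- c(st, i)
    }
    st
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- p[c(lower[-length(lower)], upper[-length(upper)]), , drop = FALSE]
  if (nrow(hull) < 3L) return(unique(hull))  # all points collinear
  hull
}

#' Convex-hull (total) area
#'
#' Area of the convex hull of a point set via monotone-chain hull plus the
#' shoelace formula; the TA metric when applied to a community's
#' (d13C, d15N) points. Degenerate inputs (fewer than 3 points, collinear
#' points) return 0.
#'
#' @param points numeric matrix or data.frame with 2 columns.
#' @return hull area (per-mil squared for isotope data).
#' @export
convex_hull_area <- function(points) {
  hull <- convex_hull(points)
  if (nrow(hull) < 3L) return(0)
  shoelace(hull)
}

shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Layman community-wide metrics
#'
#' The six community metrics of a set of (d13C, d15N) points:
#' \describe{
#'   \item{nr}{d15N range (max - min): vertical trophic structure.}
#'   \item{cr}{d13C range: basal-resource diversity.}
#'   \item{ta}{total convex-hull area: occupied isotopic niche space.}
#'   \item{cd}{mean Euclidean distance to the centroid: average trophic
#'     diversity.}
#'   \item{mnnd}{mean nearest-neighbour distance: clustering/packing.}
#'   \item{sdnnd}{sample SD of nearest-neighbour distances: evenness of
#'     packing.}
#' }
#'
#' @param points numeric matrix or data.frame with columns (d13c, d15n);
#'   typically one point per taxon (the taxon's mean corrected values).
#' @return a one-row data.frame `nr, cr, ta, cd, mnnd, sdnnd, n_points`.
#' @export
#' @examples
#' layman_metrics(rbind(c(0, 0), c(4, 0), c(0, 3)))
layman_metrics <- function(points) {
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(p)
  if (n < 2L) abort_input("insufficient data: need at least 2 points")
  d13 <- p[, 1]; d15 <- p[, 2]
  centroid <- colMeans(p)
  cd <- mean(sqrt((d13 - centroid[1])^2 + (d15 - centroid[2])^2))
  dm <- as.matrix(stats::dist(p))
  diag(dm) <- Inf
  nnd <- apply(dm, 1, min)
  nnd[!is.finite(nnd)] <- 0  # coincident-only point sets
  data.frame(
    nr = diff(range(d15)),
    cr = diff(range(d13)),
    ta = convex_hull_area(p),
    cd = cd,
    mnnd = mean(nnd),
    sdnnd = sd0(nnd),
    n_points = n)
}

#' Community points for Layman metrics
#'
#' Collapses corrected consumer samples to one point per taxon (the taxon's
#' mean corrected d13C/d15N), the community composition convention for
#' per-area metrics; set `by_individual = TRUE` to keep individual samples.
#'
#' @param consumers corrected consumer data.frame (needs `d13c_corr`,
#'   `d15n_corr`, `taxon`).
#' @param by_individual keep one point per sample instead of per taxon.
#' @return a matrix of (d13c, d15n) points.
#' @export
community_points <- function(consumers, by_individual = FALSE) {
  x <- consumers[["d13c_corr"]] %||% consumers[["d13c"]]
  y <- consumers[["d15n_corr"]] %||% consumers[["d15n"]]
  if (by_individual) return(cbind(d13c = x, d15n = y))
  mx <- tapply(x, consumers$taxon, mean)
  my <- tapply(y, consumers$taxon, mean)
  cbind(d13c = as.numeric(mx), d15n = as.numeric(my[names(mx)]))
}
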