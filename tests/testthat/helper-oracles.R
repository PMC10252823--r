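# Independent brute-force oracles and small scenario fixtures used across
# the test files.

TAXON_GROUPS_ORDER <- c("fish", "mollusk", "crustacean")

# Convex-hull area without any hull-walking algorithm: find hull edges by
# the orientation sign of every other point (an edge (i, j) has all other
# points on one side), assemble the polygon by angular sort around the
# centroid of the edge vertices, then shoelace.
oracle_hull_area <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3) return(0)
  verts <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cr <- (pts[j, 1] - pts[i, 1]) * (pts[-c(i, j), 2] - pts[i, 2]) -
        (pts[j, 2] - pts[i, 2]) * (pts[-c(i, j), 1] - pts[i, 1])
      if (all(cr >= -1e-12) || all(cr <= 1e-12)) verts <- c(verts, i, j)
    }
  }
  verts <- unique(verts)
  if (length(verts) < 3) return(0)
  v <- pts[verts, , drop = FALSE]
  ctr <- colMeans(v)
  v <- v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  k <- c(seq_len(nrow(v))[-1], 1L)
  abs(sum(x * y[k] - x[k] * y)) / 2
}

# Point-in-hull oracle: a point is in the convex hull of a set iff it lies
# in some triangle of the set (orientation-sign test per triangle).
oracle_point_in_set <- function(q, pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) return(FALSE)
  tri <- utils::combn(n, 3)
  side <- function(a, b, p) {
    (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  }
  for (t in seq_len(ncol(tri))) {
    a <- pts[tri[1, t], ]; b <- pts[tri[2, t], ]; c <- pts[tri[3, t], ]
    d1 <- side(a, b, q); d2 <- side(b, c, q); d3 <- side(c, a, q)
    if ((d1 >= -tol && d2 >= -tol && d3 >= -tol) ||
        (d1 <= tol && d2 <= tol && d3 <= tol)) {
      return(TRUE)
    }
  }
  FALSE
}

# Kruskal-Wallis H straight from its defining formula, with the standard
# tie correction, independent of stats::kruskal.test.
oracle_kw_h <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  N <- length(values)
  r <- rank(values)
  g <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# A reduced study (2 areas x 2 seasons, 6 taxa) for fast end-to-end tests.
small_scenario <- function(seed = 1L) {
  cfg <- default_scenario(seed)
  cfg$areas <- c("RM1", "RefM")
  cfg$seasons <- c("rainy", "dry")
  cfg$taxa <- data.frame(
    taxon = c("fish_a", "fish_b", "mollusk_a", "mollusk_b", "crust_a",
              "crust_b"),
    taxon_group = rep(c("fish", "mollusk", "crustacean"), each = 2),
    guild = c("piscivore", "omnivore", "planktivore", "detritivore",
              "detritivore", "omnivore"),
    n_per_cell = 3L)
  validate_scenario(cfg)
  cfg
}

# The default study with every (area, season, taxon group) cell scaled to
# exactly 20 consumers, for recovery studies.
recovery_scenario <- function(seed = 1L) {
  cfg <- default_scenario(seed)
  cfg$taxa <- data.frame(
    taxon = c(paste0("fish_", 1:5), paste0("mollusk_", 1:5),
              paste0("crust_", 1:5)),
    taxon_group = rep(c("fish", "mollusk", "crustacean"), each = 5),
    guild = rep(c("piscivore", "zoobenthivore", "planktivore", "omnivore",
                  "detritivore"), 3),
    n_per_cell = 4L)
  validate_scenario(cfg)
  cfg
}

# Fit every requested cell of a generated study and collect recovery
# statistics against the generator's ground truth.
run_recovery_study <- function(cfg, n_cells = 20, fit_seed0 = 100,
                               settings = mcmc_desk_profile()) {
  src <- generate_sources(cfg)
  srcsum <- summarize_sources(src[src$source != "seston", ])
  con <- trophic_correct(generate_consumers(cfg), cfg$guilds,
                         cfg$tdf_per_level)
  cells <- unique(con[c("area", "season", "taxon_group")])
  # locale-independent ordering: follow the scenario's own area/season order
  cells <- cells[order(match(cells$area, cfg$areas),
                       match(cells$season, cfg$seasons),
                       match(cells$taxon_group, TAXON_GROUPS_ORDER)), ]
  cells <- utils::head(cells, n_cells)
  errs <- cover <- rhats <- c()
  for (i in seq_len(nrow(cells))) {
    a <- cells$area[i]; s <- cells$season[i]; g <- cells$taxon_group[i]
    cc <- con[con$area == a & con$season == s & con$taxon_group == g, ]
    ss <- srcsum[srcsum$season == s, ]
    fit <- fit_mixing_model(cc, ss, settings = settings,
                            seed = fit_seed0 + i)
    td <- cfg$true_diets
    td <- td[td$area == a & td$season == s & td$taxon_group == g &
               td$source != "seston", ]
    tv <- stats::setNames(td$proportion, td$source)[fit$sources]
    errs <- c(errs, abs(fit$medians - tv))
    cover <- c(cover, fit$ci95["lower", ] <= tv & tv <= fit$ci95["upper", ])
    rhats <- c(rhats, fit$rhat)
  }
  list(frac_within = mean(errs <= 0.10), max_err = max(errs),
       coverage = mean(cover), max_rhat = max(rhats),
       n_cells = length(errs))
}
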