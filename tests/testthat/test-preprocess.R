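test_that("delta notation follows (R_sample/R_standard - 1) x 1000", {
  expect_equal(compute_delta(0.011, 0.011), 0)
  expect_equal(compute_delta(1.01 * 0.011, 0.011), 10, tolerance = 1e-9)
  expect_equal(compute_delta(0.98 * 0.011, 0.011), -20, tolerance = 1e-9)
  expect_error(compute_delta(-1, 0.011), "positive")
  expect_error(compute_delta(0.011, 0), "positive")
})

test_that("lipid normalization applies only above the C:N threshold", {
  expect_equal(as.numeric(lipid_normalize(-20, 4.0)), -19.36,
               tolerance = 1e-12)
  expect_equal(as.numeric(lipid_normalize(-25, 3.5)), -25)
  expect_equal(as.numeric(lipid_normalize(-25, 3.0)), -25)
  expect_warning(out <- lipid_normalize(c(-20, -21), c(NA, 4)), "C:N")
  expect_equal(as.numeric(out), c(-20, -21 - 3.32 + 0.99 * 4))
  expect_equal(attr(out, "applied"), c(FALSE, TRUE))
  expect_error(lipid_normalize(-20, -1), "positive")
})

test_that("trophic correction de-enriches by (TL - 1) per level", {
  s <- data.frame(d13c = c(-18, -20), d15n = c(8, 6))
  same <- trophic_correct(s, tl = 1)
  expect_equal(same$d13c_corr, s$d13c)
  expect_equal(same$d15n_corr, s$d15n)
  out <- trophic_correct(data.frame(d13c = -18, d15n = 8), tl = 2.4)
  expect_equal(out$d15n_corr, 8 - 1.4 * 3.4, tolerance = 1e-12)  # 3.24
  out3 <- trophic_correct(data.frame(d13c = -18, d15n = 8), tl = 3)
  expect_equal(out3$d13c_corr, -18.8, tolerance = 1e-12)
  # nitrogen correction can only lower values when TL > 1
  expect_lte(out$d15n_corr, 8)
})

test_that("correcting an already-corrected sample at TL 1 is a no-op", {
  s <- data.frame(d13c = rnorm(5, -20), d15n = rnorm(5, 6),
                  guild = "piscivore")
  tl_map <- c(piscivore = 3.0)
  once <- trophic_correct(s, tl_map)
  twice <- trophic_correct(
    data.frame(d13c = once$d13c_corr, d15n = once$d15n_corr), tl = 1)
  expect_equal(twice$d13c_corr, once$d13c_corr)
  expect_equal(twice$d15n_corr, once$d15n_corr)
})

test_that("unknown guilds fail with the offending taxa named", {
  s <- data.frame(d13c = -20, d15n = 5, guild = "kelpivore",
                  taxon = "Mystery fish")
  expect_error(trophic_correct(s, c(piscivore = 3)), "Mystery fish")
})

make_source_table <- function(a_vals, b_vals, names = c("alpha", "beta")) {
  n <- length(a_vals)
  rbind(
    data.frame(source = names[1], area = "A", season = paste0("s", 1:n),
               d13c = a_vals, d15n = a_vals),
    data.frame(source = names[2], area = "A", season = paste0("s", 1:n),
               d13c = b_vals, d15n = b_vals))
}

test_that("source screening flags correlated pairs and keeps the rest", {
  # identical series: r = 1, flagged, one member dropped
  x <- c(1, 2, 3, 4, 5, 7, 6, 9, 8, 10)
  scr <- screen_sources(make_source_table(x, x))
  expect_equal(scr$r$d13c["alpha", "beta"], 1, tolerance = 1e-12)
  expect_length(scr$retained, 1)
  # equal observation counts: alphabetical tie-break drops the later name
  expect_equal(scr$dropped, "beta")

  # perfect anticorrelation
  scr2 <- screen_sources(make_source_table(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(scr2$r$d13c["alpha", "beta"], -1, tolerance = 1e-12)

  # long independent series stay uncorrelated and both retained
  set.seed(42)
  scr3 <- screen_sources(make_source_table(rnorm(1000), rnorm(1000)))
  expect_lt(abs(scr3$r$d13c["alpha", "beta"]), 0.1)
  expect_setequal(scr3$retained, c("alpha", "beta"))
})

test_that("screening correlation is symmetric and affine-invariant", {
  set.seed(7)
  x <- rnorm(30); y <- 0.8 * x + rnorm(30, sd = 0.4)
  r_xy <- screen_sources(make_source_table(x, y))$r$d13c["alpha", "beta"]
  r_yx <- screen_sources(make_source_table(y, x))$r$d13c["alpha", "beta"]
  expect_equal(r_xy, r_yx, tolerance = 1e-12)
  r_scaled <- screen_sources(
    make_source_table(5 * x + 2, y))$r$d13c["alpha", "beta"]
  expect_equal(r_scaled, r_xy, tolerance = 1e-9)
})

test_that("configured priority overrides the drop heuristic", {
  x <- c(1, 2, 3, 4, 5, 7, 6, 9, 8, 10)
  scr <- screen_sources(make_source_table(x, x),
                        priority = c("beta", "alpha"))
  expect_equal(scr$dropped, "alpha")
})

test_that("source summaries use the n-1 SD and flag singletons", {
  src <- data.frame(source = "a", area = "A", season = "rainy",
                    d13c = c(-28, -26), d15n = c(1, 3))
  s <- summarize_sources(src)
  expect_equal(s$mu13, -27)
  expect_equal(s$sd13, sqrt(2), tolerance = 1e-12)
  expect_equal(s$n, 2)
  expect_false(s$flagged)

  single <- src[1, ]
  expect_warning(s1 <- summarize_sources(single), "single replicate")
  expect_true(s1$flagged)
  expect_true(is.na(s1$sd13))

  lit <- data.frame(source = "seagrass", mu13 = -10, sd13 = 0.8,
                    mu15 = 2, sd15 = 0.5, n = 10)
  s2 <- summarize_sources(src, literature = lit)
  expect_true("seagrass" %in% s2$source)
  expect_equal(s2$mu13[s2$source == "seagrass"], -10)
})

test_that("point-in-hull agrees with the orientation-sign oracle", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(3:4, 1)
    pts <- matrix(runif(2 * n, -5, 5), ncol = 2)
    hull <- convex_hull(pts)
    q <- runif(2, -6, 6)
    expect_equal(unname(point_in_hull(rbind(q), hull)),
                 oracle_point_in_set(q, pts),
                 info = paste("case", i))
  }
})

test_that("mixing-polygon probabilities behave at the limits", {
  ss <- data.frame(source = c("a", "b", "c"),
                   mu13 = c(-28, -18, -10), sd13 = 1e-9,
                   mu15 = c(1, 6, 1), sd15 = 1e-9)
  centroid <- data.frame(d13c_corr = mean(ss$mu13),
                         d15n_corr = mean(ss$mu15))
  chk <- mixing_polygon_check(centroid, ss, n_iter = 200, seed = 1)
  expect_gte(chk$inside_prob, 0.99)

  far <- data.frame(d13c_corr = -20 + 1000, d15n_corr = 1000)
  # envelope does not apply here: the check runs in corrected space
  expect_equal(mixing_polygon_check(far, ss, n_iter = 200,
                                    seed = 1)$inside_prob, 0)

  # zero SD reduces the Monte Carlo to a deterministic membership test
  ss0 <- ss; ss0$sd13 <- 0; ss0$sd15 <- 0
  pts <- data.frame(d13c_corr = c(-18, -30), d15n_corr = c(3, 10))
  chk0 <- mixing_polygon_check(pts, ss0, n_iter = 100, seed = 2)
  det <- point_in_hull(cbind(pts$d13c_corr, pts$d15n_corr),
                       convex_hull(cbind(ss0$mu13, ss0$mu15)))
  expect_equal(chk0$inside_prob, as.numeric(det))

  expect_error(mixing_polygon_check(centroid, ss[1:2, ], n_iter = 200),
               "geometry")
})
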