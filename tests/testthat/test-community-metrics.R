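test_that("Layman metrics reproduce the hand-computed triangle", {
  m <- layman_metrics(rbind(c(0, 0), c(4, 0), c(0, 3)))
  expect_equal(m$nr, 3, tolerance = 1e-9)
  expect_equal(m$cr, 4, tolerance = 1e-9)
  expect_equal(m$ta, 6, tolerance = 1e-9)
  expect_equal(m$cd, (5 / 3 + sqrt(73) / 3 + sqrt(52) / 3) / 3,
               tolerance = 1e-9)
  expect_equal(m$mnnd, 10 / 3, tolerance = 1e-9)
  expect_equal(m$sdnnd, sd(c(3, 4, 3)), tolerance = 1e-9)
})

test_that("degenerate point sets give zero metrics", {
  m <- layman_metrics(rbind(c(1, 2), c(1, 2)))
  expect_equal(unlist(m[c("nr", "cr", "ta", "cd", "mnnd", "sdnnd")]),
               c(nr = 0, cr = 0, ta = 0, cd = 0, mnnd = 0, sdnnd = 0))
  expect_error(layman_metrics(rbind(c(1, 2))), "insufficient")
})

test_that("hull area handles interior and collinear points", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  expect_equal(convex_hull_area(sq), 1, tolerance = 1e-12)
  expect_equal(convex_hull_area(rbind(c(0, 0), c(1, 1), c(2, 2))), 0)
  expect_equal(convex_hull_area(rbind(c(0, 0), c(1, 1))), 0)
})

test_that("hull area matches the brute-force edge oracle", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    pts <- matrix(runif(2 * n, -10, 10), ncol = 2)
    expect_equal(convex_hull_area(pts), oracle_hull_area(pts),
                 tolerance = 1e-9, info = paste("case", i))
  }
})

test_that("Layman metrics and SEA are translation invariant", {
  set.seed(5)
  pts <- matrix(rnorm(20), ncol = 2)
  shift <- matrix(rep(c(13.7, -4.2), each = 10), ncol = 2)
  m1 <- layman_metrics(pts)
  m2 <- layman_metrics(pts + shift)
  expect_equal(m1, m2, tolerance = 1e-9)
  expect_equal(standard_ellipse_area(pts)$sea,
               standard_ellipse_area(pts + shift)$sea, tolerance = 1e-9)
})

test_that("SEA follows the closed form pi sqrt(det(S))", {
  # construct points whose sample covariance is exactly the identity
  set.seed(2)
  raw <- matrix(rnorm(80), ncol = 2)
  raw <- scale(raw, center = TRUE, scale = FALSE)
  S <- cov(raw)
  white <- raw %*% solve(chol(S))
  est <- standard_ellipse_area(white)
  expect_equal(est$sea, pi, tolerance = 1e-9)

  # small-sample correction factor
  four <- matrix(rnorm(8), ncol = 2)
  e4 <- standard_ellipse_area(four)
  expect_equal(e4$sea_c, 1.5 * e4$sea, tolerance = 1e-12)

  # isotropic scaling by 2 scales the area by 4
  expect_equal(standard_ellipse_area(2 * raw)$sea,
               4 * standard_ellipse_area(raw)$sea, tolerance = 1e-9)

  # collinear clouds are degenerate with zero area
  line <- cbind(1:5, 2 * (1:5))
  expect_true(standard_ellipse_area(line)$degenerate)
  expect_equal(standard_ellipse_area(line)$sea, 0)
})

test_that("SEA_C converges to SEA from above as n grows", {
  ratios <- vapply(c(3, 5, 10, 100, 1000),
                   function(n) (n - 1) / (n - 2), numeric(1))
  expect_true(all(diff(ratios) < 0))
  expect_true(all(ratios > 1))
})

test_that("Bayesian SEA concentrates on the closed-form area", {
  sigma <- matrix(c(2, 0.7, 0.7, 1), 2)
  true_area <- pi * sqrt(det(sigma))
  set.seed(3)
  chol_s <- chol(sigma)
  meds <- vapply(c(20, 200, 2000), function(n) {
    pts <- matrix(rnorm(2 * n), ncol = 2) %*% chol_s
    sea_bayesian(pts, n_draws = 3000, seed = n)$sea_b_median
  }, numeric(1))
  expect_lt(abs(meds[2] - true_area) / true_area, 0.10)
  rel_err <- abs(meds - true_area) / true_area
  expect_lt(rel_err[3], rel_err[1])
})

test_that("SEA_B intervals are nested and seed-stable", {
  set.seed(4)
  pts <- matrix(rnorm(400), ncol = 2)
  e <- sea_bayesian(pts, n_draws = 4000, seed = 1)
  ci <- e$credible_intervals
  expect_lte(ci$`95`[1], ci$`75`[1])
  expect_lte(ci$`75`[1], ci$`50`[1])
  expect_gte(ci$`95`[2], ci$`75`[2])
  expect_gte(ci$`75`[2], ci$`50`[2])
  e2 <- sea_bayesian(pts, n_draws = 4000, seed = 99)
  expect_lt(abs(e$sea_b_median - e2$sea_b_median) / e$sea_b_median, 0.02)
  expect_error(sea_bayesian(cbind(1:5, 2 * (1:5))), "degenerate")
  expect_warning(sea_bayesian(pts, n_draws = 500, seed = 1), "noisy")
})

test_that("community points collapse to taxon means by default", {
  con <- data.frame(taxon = c("a", "a", "b"),
                    d13c_corr = c(-20, -22, -15),
                    d15n_corr = c(4, 6, 2))
  pts <- community_points(con)
  expect_equal(nrow(pts), 2)
  expect_equal(sort(pts[, "d13c"]), c(-21, -15))
  expect_equal(nrow(community_points(con, by_individual = TRUE)), 3)
})
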