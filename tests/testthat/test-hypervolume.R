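fake_result <- function(medians, area, season, group) {
  structure(list(group = list(area = area, season = season,
                              taxon_group = group),
                 sources = names(medians), medians = medians),
            class = "mixing_result")
}

test_that("niche points assemble one row per group x season", {
  meds <- function(x) stats::setNames(x / sum(x), c("a", "b", "c", "d"))
  res <- list()
  for (s in c("rainy", "nortes", "dry")) {
    for (g in c("fish", "mollusk", "crustacean")) {
      res[[paste(s, g)]] <- fake_result(meds(runif(4)), "RM1", s, g)
    }
  }
  nps <- assemble_niche_points(res)
  expect_equal(nrow(nps$points), 9)
  expect_equal(colnames(nps$points), c("a", "b", "c", "d"))
  expect_equal(nps$area, "RM1")

  bad <- res
  bad[[1]]$sources <- c("a", "b", "c", "zzz")
  expect_error(assemble_niche_points(bad), "mismatch")

  same <- list(fake_result(meds(c(1, 1, 1, 1)), "A", "rainy", "fish"),
               fake_result(meds(c(1, 1, 1, 1)), "A", "dry", "fish"))
  expect_warning(assemble_niche_points(same), "degenerate")
})

test_that("pooled z-transform standardizes across all areas jointly", {
  expect_equal(unname(z_transform(list(cbind(v = c(1, 2, 3))))$sets[[1]][, 1]),
               c(-1, 0, 1))
  set.seed(41)
  a <- matrix(runif(20), 5, 4, dimnames = list(NULL, letters[1:4]))
  b <- matrix(runif(24, 2, 3), 6, 4, dimnames = list(NULL, letters[1:4]))
  zt <- z_transform(list(A = a, B = b))
  pooled <- do.call(rbind, zt$sets)
  expect_equal(unname(colMeans(pooled)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(pooled, 2, sd)), rep(1, 4), tolerance = 1e-9)
  # applying the recorded transform again is the identity on z-scale params
  zt2 <- z_transform(zt$sets)
  expect_equal(unname(zt2$z_params$mean), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(zt2$z_params$sd), rep(1, 4), tolerance = 1e-9)

  const <- cbind(a[, 1:3], e = 1)
  expect_warning(z_transform(list(const, const)), "zero-variance")
})

test_that("hypervolume matches the 2-D Gaussian high-density-region area", {
  set.seed(42)
  pts <- matrix(rnorm(2000), 1000, 2)
  hv <- build_hypervolume(pts, mass_quantile = 0.95, n_mc = 10000,
                          seed = 1)
  target <- pi * qchisq(0.95, df = 2)  # 18.82
  expect_lt(abs(hv$volume - target) / target, 0.15)
})

test_that("hypervolume volume obeys the scaling law and nests in mass", {
  set.seed(43)
  pts <- matrix(rnorm(600), 300, 2)
  v1 <- build_hypervolume(pts, n_mc = 8000, seed = 2)$volume
  v2 <- build_hypervolume(2 * pts, n_mc = 8000, seed = 2)$volume
  expect_lt(abs(v2 / v1 - 4) / 4, 0.15)

  v50 <- build_hypervolume(pts, mass_quantile = 0.5, n_mc = 6000,
                           seed = 3)$volume
  v80 <- build_hypervolume(pts, mass_quantile = 0.8, n_mc = 6000,
                           seed = 3)$volume
  v95 <- build_hypervolume(pts, mass_quantile = 0.95, n_mc = 6000,
                           seed = 3)$volume
  expect_lt(v50, v80)
  expect_lt(v80, v95)
})

test_that("1-D mass-quantile region length matches the Gaussian interval", {
  set.seed(44)
  pts <- matrix(rnorm(1000), ncol = 1)
  hv <- build_hypervolume(pts, mass_quantile = 0.95, n_mc = 10000,
                          seed = 4)
  expect_lt(abs(hv$volume - 2 * qnorm(0.975)) / (2 * qnorm(0.975)), 0.10)
})

test_that("degenerate clouds are rejected", {
  expect_error(build_hypervolume(matrix(1, 5, 2)), "distinct")
  expect_error(build_hypervolume(cbind(rnorm(5), 1)), "zero-variance")
})

test_that("Sorensen overlap is bounded, symmetric and sane at the limits", {
  set.seed(45)
  pts <- matrix(rnorm(120), 60, 2)
  h1 <- build_hypervolume(pts, n_mc = 8000, seed = 5)
  h1b <- build_hypervolume(pts, n_mc = 8000, seed = 6)
  self <- sorensen_overlap(h1, h1b, bootstrap_reps = 0)
  expect_gte(self$sorensen, 0.95)

  far <- build_hypervolume(pts + 100, n_mc = 8000, seed = 7)
  expect_lte(sorensen_overlap(h1, far, bootstrap_reps = 0)$sorensen, 0.01)

  shifted <- build_hypervolume(pts + 0.8, n_mc = 8000, seed = 8)
  ab <- sorensen_overlap(h1, shifted, bootstrap_reps = 0)
  ba <- sorensen_overlap(shifted, h1, bootstrap_reps = 0)
  expect_lt(abs(ab$sorensen - ba$sorensen), 0.02)
  expect_true(ab$sorensen >= 0 && ab$sorensen <= 1)
  expect_lte(ab$v_intersection, min(ab$v1, ab$v2) + 1e-12)

  mism <- build_hypervolume(matrix(rnorm(90), 30, 3), n_mc = 2000, seed = 9)
  expect_error(sorensen_overlap(h1, mism), "mismatch")
})

test_that("bootstrap confidence intervals are proper probabilities", {
  set.seed(46)
  pts1 <- matrix(rnorm(60), 30, 2)
  pts2 <- matrix(rnorm(60, 0.5), 30, 2)
  h1 <- build_hypervolume(pts1, n_mc = 4000, seed = 10)
  h2 <- build_hypervolume(pts2, n_mc = 4000, seed = 11)
  ov <- sorensen_overlap(h1, h2, bootstrap_reps = 30, n_mc_boot = 1500,
                         seed = 12)
  expect_true(all(is.finite(ov$ci95)))
  expect_true(all(ov$ci95 >= 0 & ov$ci95 <= 1))
  expect_lte(ov$ci95[1], ov$ci95[2])
})
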