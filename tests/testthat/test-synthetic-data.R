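test_that("default scenario encodes the study design constants", {
  cfg <- default_scenario(seed = 1)
  expect_equal(unname(cfg$tdf_per_level), c(0.4, 3.4))
  expect_equal(cfg$guilds[["piscivore"]], 3.0)
  expect_equal(cfg$guilds[["zoobenthivore"]], 2.7)
  expect_equal(cfg$guilds[["detritivore"]], 2.4)
  c3 <- cfg$sources[cfg$sources$source == "C3_plants", ]
  expect_true(all(c3$mu13 >= -29.3 & c3$mu13 <= -26.4))
  ph <- cfg$sources[cfg$sources$source == "phytoplankton", ]
  expect_true(all(ph$mu13 >= -24.4 & ph$mu13 <= -18.1))
  expect_true(all(ph$mu15 >= 2.1 & ph$mu15 <= 4.4))
  expect_setequal(cfg$areas, c("RM1", "RM2", "RM3", "RefM"))
  expect_length(cfg$seasons, 3)
  # diets are simplex vectors and distinct between areas
  td <- cfg$true_diets
  sums <- tapply(td$proportion,
                 interaction(td$area, td$season, td$taxon_group), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  rainy_fish <- td[td$season == "rainy" & td$taxon_group == "fish", ]
  per_area <- split(rainy_fish$proportion, rainy_fish$area)
  expect_gt(max(abs(per_area$RM1 - per_area$RefM)), 0.1)
})

test_that("generation is seed-deterministic and seed-sensitive", {
  cfg <- small_scenario(seed = 5)
  expect_identical(generate_sources(cfg), generate_sources(cfg))
  expect_identical(generate_consumers(cfg), generate_consumers(cfg))
  expect_identical(generate_environment(cfg), generate_environment(cfg))
  cfg2 <- small_scenario(seed = 6)
  expect_false(isTRUE(all.equal(generate_sources(cfg)$d13c,
                                generate_sources(cfg2)$d13c)))
})

test_that("zero-SD sources collapse to their configured means", {
  cfg <- small_scenario(seed = 2)
  cfg$sources$sd13 <- 0
  cfg$sources$sd15 <- 0
  src <- generate_sources(cfg)
  key <- merge(src, cfg$sources, by = c("source", "season"))
  expect_equal(key$d13c, key$mu13, tolerance = 1e-12)
  expect_equal(key$d15n, key$mu15, tolerance = 1e-12)
})

test_that("noiseless consumers reproduce the mixture-mean formula", {
  cfg <- small_scenario(seed = 3)
  cfg$noise_sd <- c(d13c = 0, d15n = 0)
  # a trophic-level-1 'guild' eating pure C3 plants
  cfg$guilds <- c(cfg$guilds, basal_feeder = 1.0, mid_feeder = 2.4)
  cfg$taxa <- data.frame(taxon = c("pure_c3", "mid_mix"),
                         taxon_group = c("mollusk", "fish"),
                         guild = c("basal_feeder", "mid_feeder"),
                         n_per_cell = 1L)
  td <- expand.grid(area = cfg$areas, season = cfg$seasons,
                    taxon_group = c("mollusk", "fish"),
                    source = unique(cfg$sources$source),
                    stringsAsFactors = FALSE)
  td$proportion <- as.numeric(td$source == "C3_plants")
  cfg$true_diets <- td
  con <- generate_consumers(cfg)
  c3 <- cfg$sources[cfg$sources$source == "C3_plants", ]
  # TL = 1 consumer of a single source sits exactly on the source mean
  pure <- con[con$taxon == "pure_c3" & con$season == "rainy", ]
  expect_equal(pure$d13c, rep(c3$mu13[c3$season == "rainy"], nrow(pure)),
               tolerance = 1e-12)
  expect_equal(pure$d15n, rep(c3$mu15[c3$season == "rainy"], nrow(pure)),
               tolerance = 1e-12)
  # TL = 2.4 adds (2.4 - 1) * 3.4 = 4.76 per-mil of 15N enrichment
  mid <- con[con$taxon == "mid_mix" & con$season == "rainy", ]
  expect_equal(mid$d15n, rep(c3$mu15[c3$season == "rainy"] + 4.76,
                             nrow(mid)), tolerance = 1e-12)
})

test_that("group means of corrected noiseless consumers equal sum(p mu)", {
  cfg <- small_scenario(seed = 4)
  cfg$noise_sd <- c(d13c = 0, d15n = 0)
  con <- generate_consumers(cfg)
  con <- trophic_correct(con, cfg$guilds, cfg$tdf_per_level)
  mu <- cfg$sources[cfg$sources$season == "rainy", ]
  p <- cfg$true_diets
  p <- p[p$area == "RM1" & p$season == "rainy" & p$taxon_group == "fish", ]
  p <- stats::setNames(p$proportion, p$source)
  expected <- sum(p[mu$source] * mu$mu13)
  grp <- con[con$area == "RM1" & con$season == "rainy" &
               con$taxon_group == "fish", ]
  expect_equal(mean(grp$d13c_corr), expected, tolerance = 1e-9)
})

test_that("default-scenario consumers stay inside the realistic envelope", {
  # systematic component (mixture mean + trophic enrichment): within the
  # realistic envelope for every cell, independent of the noise draw
  cfg <- default_scenario(seed = 1)
  cfg$noise_sd <- c(d13c = 0, d15n = 0)
  sys <- generate_consumers(cfg)
  expect_true(all(sys$d13c >= -30 & sys$d13c <= -11))
  # with the calibrated individual noise, values stay in the reader's
  # physical envelope and only rare tail draws leave the realistic band
  for (seed in c(1, 42)) {
    con <- generate_consumers(default_scenario(seed = seed))
    expect_true(all(con$d13c >= -60 & con$d13c <= 10))
    expect_gte(mean(con$d13c >= -30 & con$d13c <= -11), 0.99)
  }
})

test_that("seston tracks phytoplankton so screening has work to do", {
  cfg <- default_scenario(seed = 8)
  src <- generate_sources(cfg)
  wide <- merge(
    src[src$source == "seston", c("area", "season", "replicate", "d13c")],
    src[src$source == "phytoplankton",
        c("area", "season", "replicate", "d13c")],
    by = c("area", "season", "replicate"))
  expect_gt(cor(wide$d13c.x, wide$d13c.y), 0.45)
})

test_that("environment tables have the design shape and obey SD = 0", {
  cfg <- default_scenario(seed = 9)
  env <- generate_environment(cfg)
  expect_equal(nrow(env), 4 * 3 * 3)
  expect_true(all(c("depth", "ph", "chlorophyll_a") %in% names(env)))
  # built-in seasonal contrast: rainy channels deeper than dry
  prof <- cfg$env_profiles[cfg$env_profiles$variable == "depth", ]
  expect_gt(mean(prof$mean[prof$season == "rainy"]),
            mean(prof$mean[prof$season == "dry"]))
  cfg$env_profiles$sd <- 0
  env0 <- generate_environment(cfg)
  prof0 <- cfg$env_profiles[cfg$env_profiles$area == "RM1" &
                              cfg$env_profiles$season == "rainy", ]
  got <- unlist(env0[env0$area == "RM1" & env0$season == "rainy", prof0$variable][1, ])
  expect_equal(unname(got), prof0$mean, tolerance = 1e-12)
})

test_that("generated tables round-trip through the readers unchanged", {
  cfg <- small_scenario(seed = 10)
  dir <- withr::local_tempdir()
  paths <- simulate_study(cfg, dir)
  con <- load_samples(paths$consumers, "consumer")
  src <- load_samples(paths$sources, "source")
  env <- load_samples(paths$environment, "environment")
  orig <- generate_consumers(cfg)
  expect_equal(con$d13c, orig$d13c, tolerance = 1e-12)
  expect_equal(con$taxon, orig$taxon)
  expect_equal(src$d13c, generate_sources(cfg)$d13c, tolerance = 1e-12)
  expect_equal(env$depth, generate_environment(cfg)$depth,
               tolerance = 1e-12)
  expect_true(file.exists(paths$scenario))
})

test_that("invalid scenario fields are rejected by name", {
  cfg <- small_scenario(seed = 1)
  cfg$sources$sd13[1] <- -1
  expect_error(generate_sources(cfg), "sources")
  cfg <- small_scenario(seed = 1)
  cfg$true_diets$proportion[1] <- cfg$true_diets$proportion[1] + 0.5
  expect_error(generate_consumers(cfg), "true_diets")
  cfg <- small_scenario(seed = 1)
  cfg$true_diets <- cfg$true_diets[cfg$true_diets$area != "RM1", ]
  expect_error(generate_consumers(cfg), "true_diets")
})
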