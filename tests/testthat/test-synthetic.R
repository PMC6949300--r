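test_that("trajectory templates satisfy their defining inequalities", {
  dense <- generate_trajectory(scenario_spec("dense_forest", noise_sd = 0))
  expect_length(dense, 16L)
  expect_true(all(dense >= 0.8))
  expect_equal(unname(diff(range(dense))), 0)

  nonf <- generate_trajectory(scenario_spec("non_forest", noise_sd = 0,
                                            params = list(level = 0.2)))
  expect_true(all(nonf == 0.2))
  expect_lt(max(nonf), 0.5)

  aff <- generate_trajectory(scenario_spec("afforestation", noise_sd = 0))
  expect_lt(aff[1], 0.5)
  expect_gte(aff[16], 0.5)
  expect_lte(sum(diff(aff > 0.5) == 1), 1)  # crosses 0.5 once, rapidly

  expect_error(scenario_spec("jungle"), "unknown archetype.*jungle")
  expect_error(scenario_spec("rotation", params = list(cycle = 1)),
               "cycle")
  expect_error(scenario_spec("recovery", params = list(onset = 1990)),
               "onset")
})

test_that("rotation trajectories alternate with the requested cycle", {
  # frozen from the segmentation stage on the noise-free template:
  # growth segments of 5 yr with 1-yr clear-cuts, truncated final phase
  tr <- generate_trajectory(scenario_spec("rotation", noise_sd = 0,
                                          params = list(cycle = 5)))
  res <- segment_series(tr)
  expect_equal(res$segments$duration, c(5, 1, 5, 1, 3))
  expect_equal(res$sse, 0, tolerance = 1e-10)
  pos <- res$segments$duration[res$segments$magnitude > 0]
  expect_lte(abs(mean(pos) - 5), 1)  # growth phases track the cycle
  # alternates across the forest threshold
  expect_gt(sum(abs(diff(tr >= 0.5))), 2)
})

test_that("trajectories are reproducible and clipped to [0, 1]", {
  for (a in archetype_names()) {
    s1 <- generate_trajectory(scenario_spec(a, noise_sd = 0.3, seed = 42))
    s2 <- generate_trajectory(scenario_spec(a, noise_sd = 0.3, seed = 42))
    expect_identical(s1, s2)
    expect_true(all(s1 >= 0 & s1 <= 1))
    # clipping never breaks the noise-free defining trajectory
    core <- generate_trajectory(scenario_spec(a, noise_sd = 0))
    expect_true(all(core >= 0 & core <= 1))
  }
})

test_that("generate_scene honours layouts and is deterministic", {
  lay <- c(dense_forest = 10, rotation = 10)
  s <- generate_scene(lay, noise_sd = 0, seed = 5)
  expect_equal(dim(s$probability), c(16L, 4L, 5L))
  expect_equal(sum(s$truth_labels == 1), 10)
  expect_equal(sum(s$truth_labels == 7), 10)
  expect_equal(s$pixel_area_ha, 25)

  s2 <- generate_scene(lay, noise_sd = 0.05, seed = 9)
  s3 <- generate_scene(lay, noise_sd = 0.05, seed = 9)
  expect_identical(s2, s3)

  lay1 <- table1_layout(1000L)
  sc <- generate_scene(lay1, noise_sd = 0, seed = 1)
  counts <- tabulate(sc$truth_labels, 8)
  expect_equal(counts / sum(counts),
               unname(lay1 / sum(lay1)))

  expect_error(generate_scene(c(dense_forest = 0)), "at least one pixel")
  expect_error(generate_scene(c(swamp = 5)), "unknown archetype")
})

test_that("benchmark density generation applies monotone laws", {
  s <- generate_scene(c(dense_forest = 8, non_forest = 8), noise_sd = 0)
  b <- generate_cdensity_benchmark(s, function(p) 100 * p, noise_sd = 0)
  expect_equal(unname(b[s$truth_labels == 1][1]), 100 * 0.9)
  expect_true(all(b >= 0))
  expect_error(generate_cdensity_benchmark(s, function(p) -p),
               "monotone")
  z <- generate_scene(c(non_forest = 4), noise_sd = 0,
                      params = list(non_forest = list(level = 0)))
  bz <- generate_cdensity_benchmark(z, function(p) 5 + 50 * p, noise_sd = 0)
  expect_true(all(bz == 5))
})

test_that("default density law matches the per-type density regime", {
  s <- generate_scene(full_layout(10), noise_sd = 0.02, seed = 2)
  b <- generate_cdensity_benchmark(s, noise_sd = 0, seed = 3)
  dense_mean <- mean(b[s$truth_labels == 1])
  nonf_mean <- mean(b[s$truth_labels == 3])
  expect_lt(abs(dense_mean - 105) / 105, 0.05)
  expect_lt(abs(nonf_mean - 22) / 22, 0.05)
})

test_that("coarse series generation injects trends, flags and noise", {
  sp <- coarse_series_spec(3, sm_trend = 0,
                           obs_noise_sd = c(vod = 0, sm = 0),
                           flag_rates = c(frozen = 0, topography = 0,
                                          urban = 0, water = 0), seed = 4)
  cs <- generate_coarse_series(sp)
  one <- cs$records[cs$records$cell == 1 & cs$records$orbit == "ascending", ]
  expect_equal(sd(one$sm), 0)  # zero trend, zero noise -> constant SM

  sp2 <- coarse_series_spec(50, sm_trend = c(rep(-0.02, 4), rep(0, 46)),
                            seed = 4)
  cs2 <- generate_coarse_series(sp2)
  expect_equal(mean(cs2$truth$sm_trend < 0), 0.08)
  expect_setequal(unique(cs2$records$orbit), c("ascending", "descending"))

  expect_identical(generate_coarse_series(sp), generate_coarse_series(sp))
  expect_error(coarse_series_spec(3, dates = as.Date(character(0))),
               "no dates")
  expect_error(coarse_series_spec(3, flag_rates = c(frozen = 2,
                                                    topography = 0,
                                                    urban = 0, water = 0)),
               "flag rates")
})

test_that("province tables pass through the stated anchors", {
  tb <- generate_province_tables(seed = 10)
  regional <- tapply(tb$emissions$value, tb$emissions$year, sum)
  expect_equal(unname(regional[["1997"]]), 0.21, tolerance = 1e-12)
  expect_equal(unname(regional[["2012"]]), 0.63, tolerance = 1e-12)
  expect_equal(unname(regional[["2015"]]), 0.63, tolerance = 1e-12)
  expect_true(all(tb$emissions$units == "PgC"))

  const <- generate_province_tables(timber_shape = 1000, share_noise_sd = 0,
                                    n_provinces = 4, seed = 1)
  expect_true(all(abs(const$timber$volume - 250) < 1e-9))

  a <- generate_province_tables(seed = 1)
  b <- generate_province_tables(seed = 2)
  # seeds perturb only the share noise: regional totals agree exactly
  expect_equal(tapply(a$emissions$value, a$emissions$year, sum),
               tapply(b$emissions$value, b$emissions$year, sum),
               tolerance = 1e-12)
  expect_false(identical(a$emissions$value, b$emissions$value))

  # timber ramp is anchored in carbon units
  vol <- tapply(a$timber$volume, a$timber$year, sum)
  expect_equal(unname(timber_carbon(vol[["2003"]])), 0.004,
               tolerance = 1e-9)
  expect_equal(unname(timber_carbon(vol[["2017"]])), 0.012,
               tolerance = 1e-9)
})
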