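# Build a segmentation_result directly (for unit tests of the index and
# rule layers).
mock_segments <- function(mag, dur) {
  yrs <- cumsum(c(2002, dur))
  seg <- data.frame(start_year = yrs[-length(yrs)], end_year = yrs[-1],
                    start_value = 0.5, end_value = 0.5 + mag)
  seg$duration <- dur
  seg$magnitude <- mag
  seg$direction <- sign(mag)
  structure(list(segments = seg, sse = 0, n_segments = length(mag)),
            class = "segmentation_result")
}

test_that("disturbance indices follow the magnitude/duration definition", {
  r <- disturbance_indices(mock_segments(c(0.6, -0.1), c(2, 3)))
  expect_equal(r$increase_index, 0.3)
  expect_equal(r$increase_category, "low")
  expect_equal(r$decrease_index, 0.1 / 3)
  expect_equal(r$decrease_category, "very_low")

  decl <- disturbance_indices(mock_segments(c(-0.2, -0.3), c(4, 4)))
  expect_equal(decl$increase_index, 0)

  hi <- disturbance_indices(mock_segments(0.9, 1))
  expect_equal(hi$increase_index, 0.9)
  expect_equal(hi$increase_category, "high")

  # indices invariant under adding flat (zero-magnitude) segments
  a <- disturbance_indices(mock_segments(c(0.5, -0.4), c(2, 2)))
  b <- disturbance_indices(mock_segments(c(0, 0.5, 0, -0.4), c(3, 2, 1, 2)))
  expect_equal(a$increase_index, b$increase_index)
  expect_equal(a$decrease_index, b$decrease_index)
})

test_that("the nine dynamics classes match their definitions", {
  years <- 2002:2017
  cls <- function(y) {
    r <- segment_series(y, years)
    dynamics_class(y, r)
  }
  expect_equal(cls(rep(0.9, 16)), 1L)
  expect_equal(cls(rep(0.6, 16)), 2L)
  expect_equal(cls(rep(0.3, 16)), 3L)
  expect_equal(cls(seq(0.3, 0.7, length.out = 16)), 4L)
  expect_equal(cls(seq(0.7, 0.3, length.out = 16)), 6L)
  # up with a clear-cut on the way -> class 5
  y5 <- c(seq(0.2, 0.8, length.out = 8), 0.1,
          seq(0.2, 0.8, length.out = 7))
  expect_equal(cls(y5), 5L)
  # down with rapid regrowth on the way -> class 7
  expect_equal(cls(rev(y5)), 7L)
  # fluctuating, non-forest at both ends -> 8; forest at both ends -> 9
  y8 <- c(rep(0.3, 4), rep(0.8, 6), rep(0.3, 6))
  expect_equal(cls(y8), 8L)
  y9 <- c(rep(0.8, 4), 0.2, 0.2, rep(0.8, 10))
  expect_equal(cls(y9), 9L)
})

test_that("land-use rule table reproduces the documented examples", {
  idx <- function(i, d) list(increase_index = i, decrease_index = d)
  expect_equal(names(landuse_type(idx(0.05, 0.02), 1)), "dense_forest")
  expect_equal(names(landuse_type(idx(0.8, 0), 4)), "afforestation")
  expect_equal(names(landuse_type(idx(0.45, 0.7), 7)), "rotation_L")
  expect_equal(names(landuse_type(idx(0.1, 0), 4)), "recovery")
  expect_equal(names(landuse_type(idx(0.5, 0.5), 8)), "rotation")
  expect_equal(names(landuse_type(idx(0.1, 0.1), 9)), "forest")
  expect_equal(names(landuse_type(idx(0.1, 0.1), 8)), "non_forest")
  expect_equal(names(landuse_type(idx(0.9, 0.9), 6)), "deforestation")
})

test_that("the 8-type classifier is total and deterministic", {
  grid <- seq(0, 1, by = 0.25)
  for (dyn in 1:9) for (i in grid) for (d in grid) {
    code <- landuse_type(list(increase_index = i, decrease_index = d), dyn)
    expect_true(code %in% 1:8)
    expect_identical(
      code,
      landuse_type(list(increase_index = i, decrease_index = d), dyn))
  }
})

test_that("time reversal swaps classes 4<->6, 5<->7 and the indices", {
  years <- 2002:2017
  set.seed(55)
  cases <- c(lapply(archetype_names(), function(a)
    unname(generate_trajectory(scenario_spec(a)))),
    lapply(1:20, function(i) random_series(16)))
  swap <- c(`1` = 1L, `2` = 2L, `3` = 3L, `4` = 6L, `5` = 7L, `6` = 4L,
            `7` = 5L, `8` = 8L, `9` = 9L)
  for (y in cases) {
    fw <- segment_series(y, years)
    bw <- segment_series(rev(y), years)
    df <- dynamics_class(y, fw)
    db <- dynamics_class(rev(y), bw)
    expect_equal(db, unname(swap[as.character(df)]))
    i_f <- disturbance_indices(fw)
    i_b <- disturbance_indices(bw)
    expect_equal(i_b$increase_index, i_f$decrease_index, tolerance = 1e-7)
    expect_equal(i_b$decrease_index, i_f$increase_index, tolerance = 1e-7)
  }
})

test_that("classify_scene labels every valid pixel and partitions area", {
  s <- generate_scene(c(dense_forest = 12), noise_sd = 0, seed = 1)
  cl <- classify_scene(s)
  expect_true(all(cl$labels == 1))
  expect_equal(cl$summary$fraction[1], 1)

  s2 <- generate_scene(full_layout(12), noise_sd = 0.02, seed = 3)
  cl2 <- classify_scene(s2, diagnostics = TRUE)
  expect_equal(sum(cl2$summary$count) + cl2$n_masked, 96L)
  expect_equal(sum(cl2$summary$fraction), 1)
  expect_true(all(cl2$diagnostics$dynamics %in% 1:9))

  # masked pixels (unsegmentable series) are counted, not mislabelled
  s2$probability[3:8, 1, 1] <- NA
  cl3 <- classify_scene(s2)
  expect_true(is.na(cl3$labels[1, 1]))
  expect_equal(cl3$n_masked, 1L)
})

test_that("noise-free typology recovers the truth archetypes", {
  s <- generate_scene(full_layout(20), noise_sd = 0, seed = 17)
  cl <- classify_scene(s)
  expect_gte(mean(cl$labels == s$truth_labels), 0.95)
})
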