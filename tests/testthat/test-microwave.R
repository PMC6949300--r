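make_records <- function(n = 60, seed = 5) {
  withr::local_seed(seed)
  data.frame(cell = 1L,
             date = seq(as.Date("2012-01-05"), by = 5, length.out = n),
             orbit = "ascending",
             vod = 0.5 + rnorm(n, 0, 0.02),
             sm = 0.25 + rnorm(n, 0, 0.01),
             soil_temp = 285, tb_rmse = runif(n, 1, 8),
             flag_frozen = FALSE, flag_topography = FALSE,
             flag_urban = FALSE, flag_water = FALSE)
}

test_that("quality filtering applies every exclusion criterion", {
  r <- make_records(10)
  r$tb_rmse[1] <- 12          # RFI proxy above 10 K
  r$soil_temp[2] <- 270       # frozen soil
  r$flag_urban[3] <- TRUE
  out <- quality_filter(r)
  expect_equal(nrow(out), 7L)
  expect_false(any(out$tb_rmse > 10))
  expect_false(any(out$soil_temp < 273.5))
  rem <- attr(out, "removed")
  expect_equal(unname(rem), c(1L, 1L, 1L))

  # order independence: permuting records keeps the same retained set
  perm <- r[sample(nrow(r)), ]
  out2 <- quality_filter(perm)
  expect_setequal(out2$date, out$date)

  # boundary: exactly 10 K is retained, exactly 273.5 K is retained
  rb <- make_records(6)
  rb$tb_rmse[1] <- 10
  rb$soil_temp[2] <- 273.5
  expect_equal(nrow(quality_filter(rb)), 6L)
})

test_that("VOD smoothing excludes percentile outliers once", {
  const <- make_records(40)
  const$vod <- 0.5
  out <- smooth_and_deoutlier_vod(const)
  expect_equal(nrow(out), 40L)  # degenerate residues: nothing excluded
  expect_equal(out$vod_smooth, rep(0.5, 40))

  r <- make_records(100, seed = 8)
  out2 <- smooth_and_deoutlier_vod(r)
  excl <- attr(out2, "n_excluded")
  sm <- landcarbon:::.moving_average_days(r$date, r$vod, 30)
  res <- r$vod - sm
  qs <- quantile(res, c(0.1, 0.9), names = FALSE)
  expect_equal(excl, sum(res < qs[1]) + sum(res > qs[2]))
  expect_lte(sum(res < qs[1]), 10)
  expect_lte(sum(res > qs[2]), 10)

  spike <- make_records(30, seed = 9)
  spike$vod[15] <- spike$vod[15] + 1
  out3 <- smooth_and_deoutlier_vod(spike)
  expect_false(spike$date[15] %in% out3$date)

  expect_error(smooth_and_deoutlier_vod(make_records(4)), "at least 5")
})

test_that("orbit combination keeps the 30 lowest TB-RMSE per year", {
  withr::local_seed(3)
  mk <- function(n, orbit, year) {
    r <- make_records(n)
    r$orbit <- orbit
    r$date <- as.Date(paste0(year, "-01-01")) + sort(sample(360, n))
    r$tb_rmse <- runif(n, 0, 9)
    r
  }
  asc <- mk(25, "ascending", 2013)
  desc <- mk(20, "descending", 2013)
  out <- combine_orbits(asc, desc)
  expect_equal(nrow(out), 30L)
  discarded_min <- min(setdiff(c(asc$tb_rmse, desc$tb_rmse), out$tb_rmse))
  expect_true(all(out$tb_rmse <= discarded_min))

  few <- combine_orbits(mk(7, "ascending", 2014), mk(5, "descending", 2014))
  expect_equal(nrow(few), 12L)

  # ties resolve by date, earliest first
  tie <- mk(40, "ascending", 2015)
  tie$tb_rmse <- 5
  kept <- combine_orbits(tie[0, ], tie)
  expect_equal(kept$date, sort(tie$date)[1:30])

  # output size never exceeds the cap
  big <- combine_orbits(mk(60, "ascending", 2016), mk(60, "descending", 2016))
  expect_true(all(table(format(big$date, "%Y")) <= 30))
})

test_that("logistic VOD calibration recovers a known law", {
  withr::local_seed(21)
  vodr <- runif(80, 0.15, 0.95)
  law <- function(v) 12 + (125 - 12) / (1 + exp((0.5 - v) / 0.1))
  cal <- fit_vod_calibration(vodr, law(vodr))
  truth <- c(A = 12, B = 125, xmid = 0.5, scal = 0.1)
  expect_true(all(abs(cal$coef - truth) / truth < 0.05))
  v_new <- seq(0.1, 1, by = 0.01)
  expect_true(all(abs(predict(cal, v_new) - law(v_new)) /
                    law(v_new) < 0.02))
  # monotone: higher VOD never maps to lower density
  expect_true(all(diff(predict(cal, v_new)) >= 0))
  expect_error(fit_vod_calibration(rep(0.5, 30), runif(30)), "degenerate")
})

test_that("averaging two identical benchmark calibrations is the identity", {
  withr::local_seed(6)
  dens <- setNames(12 + (125 - 12) /
                     (1 + exp((0.5 - runif(40, 0.2, 0.9)) / 0.1)), 1:40)
  vod <- data.frame(cell = rep(1:40, each = 8),
                    year = rep(2010:2017, times = 40))
  vod$vod <- qlogis((unname(dens[vod$cell]) - 12) / (125 - 12)) * 0.1 + 0.5
  one <- vod_to_cdensity(vod, dens)
  two <- vod_to_cdensity(vod, list(dens, dens))
  expect_equal(two$series$cdensity, one$series$cdensity, tolerance = 1e-9)
})

test_that("cell trends detect exact declines and respect test size", {
  exact <- data.frame(cell = 1L, year = 2010:2017,
                      value = 0.3 - 0.01 * (0:7))
  tr <- cell_trends(exact)
  expect_equal(tr$trends$slope, -0.01, tolerance = 1e-12)
  expect_lt(tr$trends$p_value, 1e-10)
  expect_true(tr$trends$significant_decline)

  mk <- cell_trends(exact, method = "mann_kendall")
  expect_equal(mk$trends$slope, -0.01, tolerance = 1e-12)
  expect_true(mk$trends$significant_decline)

  # null cells: one-sided size ~ alpha/2 (small-sample sanity check;
  # the full 2000-cell calibration lives in the acceptance suite)
  withr::local_seed(14)
  null_df <- data.frame(cell = rep(1:300, each = 8),
                        year = rep(2010:2017, 300),
                        value = rnorm(2400, 0.3, 0.01))
  fr <- cell_trends(null_df)$summary$significant_decline_fraction
  expect_lt(fr, 0.06)

  short <- data.frame(cell = 1L, year = 2010:2012, value = 1:3)
  expect_equal(cell_trends(short)$summary$n_masked, 1L)
})

test_that("annualization averages surviving observations per year", {
  r <- make_records(20)
  r$vod <- rep(c(0.4, 0.6), 10)
  ann <- annualize(r, "vod")
  expect_equal(ann$value, tapply(r$vod, format(r$date, "%Y"), mean),
               ignore_attr = TRUE)
})
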