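## L-band VOD / soil-moisture observation filtering, smoothing, orbit
## combination, logistic biomass calibration and per-cell trend tests.

#' Quality-filter coarse-grid microwave records
#'
#' Removes observations with any set scene flag (strong topography,
#' urban, water, frozen), frozen soils (soil temperature below 273.5 K)
#' or a TB-RMSE above 10 K (radio-frequency-interference proxy).
#' Removal counts per criterion are attached as attribute `"removed"`.
#' Filtering is order-independent.
#'
#' @param records data.frame as produced by [generate_coarse_series()].
#' @param tb_rmse_max TB-RMSE exclusion threshold, K (default 10).
#' @param frozen_temp soil-temperature threshold, K (default 273.5).
#' @return the retained records, with a `"removed"` attribute.
#' @export
quality_filter <- function(records, tb_rmse_max = 10, frozen_temp = 273.5) {
  flags <- records$flag_frozen | records$flag_topography |
    records$flag_urban | records$flag_water
  frozen <- records$soil_temp < frozen_temp
  rfi <- records$tb_rmse > tb_rmse_max
  keep <- !(flags | frozen | rfi)
  out <- records[keep, , drop = FALSE]
  attr(out, "removed") <- c(flagged = sum(flags),
                            frozen = sum(frozen & !flags),
                            tb_rmse = sum(rfi & !flags & !frozen))
  out
}

# Centered calendar-window moving average: for each observation, the
# mean of values within +/- window_days/2 days; edges use the truncated
# window.
.moving_average_days <- function(dates, values, window_days) {
  d <- as.numeric(dates)
  half <- window_days / 2
  lo <- findInterval(d - half, d, left.open = TRUE) + 1L
  hi <- findInterval(d + half, d)
  cs <- cumsum(c(0, values))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a VOD series and remove residual outliers
#'
#' Applies a centered 30-day moving average to one cell-and-orbit VOD
#' series, computes residues (raw minus smoothed), excludes observations
#' whose residue falls strictly below the 10th or strictly above the
#' 90th percentile of residues, then recomputes the smoothed series on
#' the survivors. On a degenerate (all-equal-residue) series nothing is
#' excluded. The percentile exclusion is applied once.
#'
#' @param records data.frame for a single cell and orbit with `date`
#'   and `vod` columns, sorted by date.
#' @param window_days smoothing window size, days (default 30).
#' @param percentiles lower/upper residue percentiles (default 0.1/0.9,
#'   linear interpolation).
#' @return the surviving records with a `vod_smooth` column.
#' @export
smooth_and_deoutlier_vod <- function(records, window_days = 30,
                                     percentiles = c(0.1, 0.9)) {
  if (nrow(records) < 5L) stop("need at least 5 observations",
                               call. = FALSE)
  stopifnot(!is.unsorted(as.numeric(records$date)))
  sm <- .moving_average_days(records$date, records$vod, window_days)
  res <- records$vod - sm
  qs <- quantile(res, percentiles, names = FALSE, type = 7)
  keep <- res >= qs[1] & res <= qs[2]
  out <- records[keep, , drop = FALSE]
  out$vod_smooth <- .moving_average_days(out$date, out$vod, window_days)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Combine ascending and descending VOD series
#'
#' Per calendar year, pools both orbits and keeps only the
#' `keep_per_year` observations with the lowest TB-RMSE (all kept when
#' fewer exist); ties at the cutoff resolve by date order, earliest
#' first.
#'
#' @param asc,desc filtered record data.frames (need `date`, `tb_rmse`).
#' @param keep_per_year observations retained per year (default 30).
#' @return combined records sorted by date.
#' @export
combine_orbits <- function(asc, desc, keep_per_year = 30L) {
  all_rec <- rbind(asc, desc)
  if (!nrow(all_rec)) return(all_rec)
  yr <- as.integer(format(as.Date(all_rec$date), "%Y"))
  kept <- lapply(split(seq_len(nrow(all_rec)), yr), function(idx) {
    o <- idx[order(all_rec$tb_rmse[idx], as.numeric(all_rec$date[idx]))]
    o[seq_len(min(keep_per_year, length(o)))]
  })
  out <- all_rec[sort(unlist(kept, use.names = FALSE)), , drop = FALSE]
  out[order(as.numeric(out$date)), , drop = FALSE]
}

#' Fit a four-parameter logistic VOD-to-carbon-density calibration
#'
#' Fits density = A + (B - A) / (1 + exp((xmid - vod) / scal)) between
#' reference-period mean VOD and benchmark density across cells
#' (monotone increasing for positive `scal`).
#'
#' @param vod_ref per-cell reference-period mean VOD.
#' @param density per-cell benchmark carbon density, Mg C/ha.
#' @return object of class `"vod_calibration"` with coefficients
#'   A, B, xmid, scal.
#' @export
fit_vod_calibration <- function(vod_ref, density) {
  ok <- is.finite(vod_ref) & is.finite(density)
  vod_ref <- vod_ref[ok]; density <- density[ok]
  if (length(vod_ref) < 5L) stop("too few cells for calibration",
                                 call. = FALSE)
  if (sd(vod_ref) < 1e-10)
    stop("degenerate (constant) VOD: cannot calibrate", call. = FALSE)
  df <- data.frame(x = vod_ref, y = density)
  fit <- suppressWarnings(
    nls(y ~ SSfpl(x, A, B, xmid, scal), data = df,
        control = stats::nls.control(maxiter = 200, warnOnly = TRUE)))
  co <- coef(fit)
  if (co[["scal"]] <= 0 || co[["B"]] < co[["A"]]) {
    # enforce the monotone-increasing saturating form
    co <- c(A = min(density), B = max(density),
            xmid = unname(median(vod_ref)), scal = sd(vod_ref))
    fit2 <- try(nls(y ~ A + (B - A) / (1 + exp((xmid - x) / scal)),
                    data = df, start = as.list(co),
                    lower = c(A = 0, B = 0, xmid = -Inf, scal = 1e-6),
                    algorithm = "port"), silent = TRUE)
    if (!inherits(fit2, "try-error")) co <- coef(fit2)
  }
  structure(list(coef = co), class = "vod_calibration")
}

#' @export
predict.vod_calibration <- function(object, newdata, ...) {
  co <- object$coef
  x <- if (is.data.frame(newdata)) newdata$x else as.numeric(newdata)
  co[["A"]] + (co[["B"]] - co[["A"]]) /
    (1 + exp((co[["xmid"]] - x) / co[["scal"]]))
}

#' Convert a VOD series to carbon density via benchmark calibration
#'
#' Calibrates VOD against one or two benchmark density maps (aggregated
#' to the coarse grid) over a reference period and applies the fitted
#' logistic curve(s) to the full series; with two benchmarks the two
#' calibrated series are averaged.
#'
#' @param vod data.frame with `cell`, `date` (or `year`) and `vod`.
#' @param benchmarks a per-cell density vector, or a list of one or two
#'   such vectors (indexable by cell id).
#' @param ref_period optional year range defining the reference period
#'   for the per-cell mean VOD (default: all years).
#' @return list with `series` (input plus a `cdensity` column) and
#'   `calibrations` (list of `vod_calibration` fits).
#' @export
vod_to_cdensity <- function(vod, benchmarks, ref_period = NULL) {
  if (!is.list(benchmarks) || is.data.frame(benchmarks))
    benchmarks <- list(benchmarks)
  yr <- if ("year" %in% names(vod)) vod$year
  else as.integer(format(as.Date(vod$date), "%Y"))
  sel <- if (is.null(ref_period)) rep(TRUE, nrow(vod)) else yr %in% ref_period
  ref <- tapply(vod$vod[sel], vod$cell[sel], mean)
  cells <- as.integer(names(ref))
  fits <- lapply(benchmarks, function(b)
    fit_vod_calibration(as.numeric(ref), as.numeric(b[cells])))
  preds <- vapply(fits, predict, numeric(nrow(vod)), newdata = vod$vod)
  vod$cdensity <- rowMeans(preds)
  list(series = vod, calibrations = fits)
}

# Closed-form per-group OLS slope + two-sided t-test, vectorised over
# cells.
.ols_trend <- function(years, values) {
  n <- length(years)
  mx <- mean(years); my <- mean(values)
  sxx <- sum((years - mx)^2)
  b <- sum((years - mx) * (values - my)) / sxx
  res <- values - my - b * (years - mx)
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tval <- if (se > 0) b / se else sign(b) * Inf
  p <- 2 * pt(-abs(tval), n - 2)
  c(slope = b, p_value = p)
}

.mk_trend <- function(years, values) {
  ct <- suppressWarnings(stats::cor.test(years, values, method = "kendall"))
  # Sen slope: median of pairwise slopes
  cmb <- combn(length(years), 2)
  slopes <- (values[cmb[2, ]] - values[cmb[1, ]]) /
    (years[cmb[2, ]] - years[cmb[1, ]])
  c(slope = median(slopes), p_value = unname(ct$p.value))
}

#' Per-cell trends with significance
#'
#' Least-squares slope of annual means per cell with a two-sided t-test
#' (default), or Mann-Kendall test with Sen slope. Cells with fewer than
#' `min_years` annual values are masked. The summary reports the
#' fraction of valid cells with a significant decline (slope < 0 and
#' p < alpha).
#'
#' @param annual data.frame with `cell`, `year`, `value` (already
#'   annualised, e.g. via [annualize()]).
#' @param alpha significance level (default 0.05).
#' @param method `"ols"` or `"mann_kendall"`.
#' @param min_years minimum annual values per cell (default 4).
#' @return list with `trends` (data.frame: cell, slope, p_value,
#'   n_years, significant_decline) and `summary` (n_cells, n_masked,
#'   significant_decline_fraction).
#' @export
cell_trends <- function(annual, alpha = 0.05,
                        method = c("ols", "mann_kendall"), min_years = 4L) {
  method <- match.arg(method)
  fun <- if (method == "ols") .ols_trend else .mk_trend
  grp <- split(annual[c("year", "value")], annual$cell)
  rows <- lapply(names(grp), function(cl) {
    g <- grp[[cl]]
    if (nrow(g) < min_years)
      return(data.frame(cell = cl, slope = NA_real_, p_value = NA_real_,
                        n_years = nrow(g), significant_decline = NA))
    tr <- fun(g$year, g$value)
    data.frame(cell = cl, slope = tr[["slope"]], p_value = tr[["p_value"]],
               n_years = nrow(g),
               significant_decline = tr[["slope"]] < 0 &&
                 tr[["p_value"]] < alpha)
  })
  trends <- do.call(rbind, rows)
  valid <- !is.na(trends$significant_decline)
  list(trends = trends,
       summary = list(n_cells = sum(valid), n_masked = sum(!valid),
                      significant_decline_fraction =
                        if (any(valid)) mean(trends$significant_decline[valid])
                      else NA_real_))
}

#' Annualise observations by calendar-year means
#'
#' @param records data.frame with `cell`, `date` (or `year`) and a value
#'   column.
#' @param value name of the value column.
#' @return data.frame with `cell`, `year`, `value`.
#' @export
annualize <- function(records, value = "vod") {
  yr <- if ("year" %in% names(records)) records$year
  else as.integer(format(as.Date(records$date), "%Y"))
  agg <- stats::aggregate(records[[value]],
                          by = list(cell = records$cell, year = yr), mean)
  names(agg)[3] <- "value"
  agg[order(agg$cell, agg$year), ]
}
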