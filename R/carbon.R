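## Benchmark-calibrated carbon-density modelling and per-type carbon
## stock, gross-flux, net-sink and emission-offset accounting.

#' Convert a CO2 mass to carbon mass
#'
#' @param x value(s) in CO2 mass units (any magnitude unit).
#' @return the same value(s) in C mass units (divided by 3.67).
#' @export
co2_to_c <- function(x) {
  assert_nonneg(x, "CO2 value")
  x / 3.67
}

#' Carbon content of harvested timber
#'
#' Biomass is volume times wood basic density; carbon is half the
#' biomass.
#'
#' @param volume timber volume, m3.
#' @param wood_density wood basic density, Mg per m3 (default 0.45, an
#'   average for pine, cedar and eucalyptus).
#' @return carbon, Pg C.
#' @export
timber_carbon <- function(volume, wood_density = 0.45) {
  assert_nonneg(volume, "volume"); assert_nonneg(wood_density, "wood density")
  volume * wood_density * 0.5 * 1e-9
}

#' Carbon stock of a density map
#'
#' @param density row x col carbon-density matrix, Mg C/ha.
#' @param mask optional logical matrix selecting pixels.
#' @param pixel_area_ha pixel area, hectares (default 25 = 500 m grid).
#' @return stock in Pg C.
#' @export
stock <- function(density, mask = NULL, pixel_area_ha = 25) {
  v <- as.numeric(density)
  if (!is.null(mask)) v <- v[as.logical(mask)]
  v <- v[!is.na(v)]
  if (any(v < 0)) stop("negative carbon densities", call. = FALSE)
  sum(v) * pixel_area_ha * 1e-9
}

#' Train the benchmark-calibrated carbon-density model
#'
#' Boosted regression trees mapping per-pixel predictors (reflectance
#' bands, indices, elevation) to benchmark carbon density. Half the
#' pixels (by default) train the model; the held-out half provides the
#' quality metrics: correlation r, the slope of predicted on benchmark
#' density, and RMSE in Mg C/ha.
#'
#' @param benchmark row x col benchmark density matrix (Mg C/ha).
#' @param predictors named list of row x col matrices aligned with the
#'   benchmark.
#' @param split training fraction (default 0.5).
#' @param seed integer seed.
#' @param n_rounds,max_depth,shrinkage boosting controls.
#' @return object of class `"cdensity_model"` with `model` and `quality`
#'   (`r`, `slope`, `rmse`, `n_train`, `n_test`).
#' @export
train_cdensity_model <- function(benchmark, predictors, split = 0.5,
                                 seed = 1L, n_rounds = 400L, max_depth = 3L,
                                 shrinkage = 0.1) {
  stopifnot(is.list(predictors), length(predictors) >= 1L,
            split > 0, split < 1)
  for (p in predictors)
    if (!identical(dim(p), dim(benchmark)))
      stop("predictor rasters must align with the benchmark", call. = FALSE)
  X <- vapply(predictors, as.numeric, numeric(length(benchmark)))
  colnames(X) <- names(predictors)
  y <- as.numeric(benchmark)
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (length(y) < 100L) stop("need at least 100 pixels", call. = FALSE)
  idx <- with_seed(seed, sample.int(length(y), floor(split * length(y))))
  model <- boosted_trees(X[idx, , drop = FALSE], y[idx],
                         n_rounds = n_rounds, max_depth = max_depth,
                         shrinkage = shrinkage, seed = seed)
  pred <- predict(model, X[-idx, , drop = FALSE])
  obs <- y[-idx]
  quality <- list(
    r = if (sd(pred) > 1e-12) cor(pred, obs) else 0,
    slope = unname(coef(lm(pred ~ obs))[2]),
    rmse = sqrt(mean((pred - obs)^2)),
    n_train = length(idx), n_test = length(obs))
  structure(list(model = model, predictors = names(predictors),
                 quality = quality),
            class = "cdensity_model")
}

#' Predict a carbon-density map
#'
#' @param object a [train_cdensity_model()] result.
#' @param predictors named list of aligned predictor matrices.
#' @return row x col density matrix (Mg C/ha, floored at 0).
#' @export
predict_cdensity <- function(object, predictors) {
  stopifnot(inherits(object, "cdensity_model"))
  X <- vapply(predictors, as.numeric, numeric(length(predictors[[1]])))
  out <- rep(NA_real_, nrow(X))
  ok <- stats::complete.cases(X)
  out[ok] <- pmax(0, predict(object$model, X[ok, , drop = FALSE]))
  matrix(out, nrow = nrow(predictors[[1]]))
}

# Mixed-precision rounding used by the printed accounting tables:
# integer percent except values below 1 in magnitude, kept at one
# significant digit (0.78 -> 0.8, -0.061 -> -0.06).
round_contribution <- function(x) {
  ifelse(abs(x) < 1, signif(x, 1), round(x))
}

#' Contribution of each type's net sink to the regional sink
#'
#' @param net_sinks named numeric vector of per-type net sinks
#'   (Pg C/yr).
#' @return list with `regional_sink`, raw `contribution` (percent,
#'   summing to 100) and `contribution_rounded` (integer percent,
#'   sub-1% values at one significant digit).
#' @export
sink_contributions <- function(net_sinks) {
  tot <- sum(net_sinks)
  if (abs(tot) < 1e-15) stop("regional net sink is zero", call. = FALSE)
  contrib <- net_sinks / tot * 100
  list(regional_sink = tot, contribution = contrib,
       contribution_rounded = round_contribution(contrib))
}

#' Share of each type in the regional carbon stock
#'
#' @param stocks named per-type stocks (Pg C).
#' @return percent shares summing to 100.
#' @export
stock_shares <- function(stocks) {
  assert_nonneg(stocks, "stocks")
  stocks / sum(stocks) * 100
}

#' Emission-offset fraction of a net sink
#'
#' Net sink divided by mean annual fossil carbon emissions over the
#' averaging window, in percent. Both the ratio-of-means (default) and
#' the mean of year-wise ratios are available, since printed per-type
#' offsets are not reproducible without knowing the averaging scheme.
#'
#' @param net_sink net sink, Pg C/yr (scalar or vector).
#' @param emissions data.frame with `year` and `value` columns (Pg C;
#'   convert CO2 first with [co2_to_c()]), or a numeric vector of annual
#'   regional emissions.
#' @param window years to average over (default 2002:2015).
#' @param scheme `"ratio_of_means"` or `"yearwise_mean"`.
#' @return offset fraction(s), percent.
#' @export
offset_fraction <- function(net_sink, emissions, window = 2002:2015,
                            scheme = c("ratio_of_means", "yearwise_mean")) {
  scheme <- match.arg(scheme)
  annual <- if (is.data.frame(emissions)) {
    tapply(emissions$value, emissions$year, sum)
  } else emissions
  yrs <- as.numeric(names(annual) %||% seq_along(annual))
  keep <- yrs %in% window
  if (!any(keep)) stop("no emission years overlap the window", call. = FALSE)
  annual <- annual[keep]
  switch(scheme,
         ratio_of_means = net_sink / mean(annual) * 100,
         yearwise_mean = vapply(net_sink,
                                function(s) mean(s / annual) * 100,
                                numeric(1)))
}

#' Per-type and regional carbon account
#'
#' Computes annual per-type stocks from a density stack and a land-use
#' map, then per type and for the whole region: start/end stocks, gross
#' gains and losses (sums of positive/negative year-to-year stock
#' deltas), the net sink, mean density, the contribution to the regional
#' sink and the emission-offset fraction.
#'
#' @param density_stack list with `density` (year x row x col, Mg C/ha)
#'   and `years`.
#' @param landuse row x col integer type map (1..8, NA = masked), e.g.
#'   `classify_scene()$labels`.
#' @param emissions emissions table or vector (Pg C; see
#'   [offset_fraction()]), or NULL to skip offsets.
#' @param pixel_area_ha pixel area in hectares.
#' @param emissions_window averaging window for offsets.
#' @param sink_method `"endpoint"` (stock difference over n_years - 1)
#'   or `"ols_slope"` (least-squares slope of annual stocks).
#' @return object of class `"carbon_account"`: list with `by_type`
#'   data.frame, `regional` list, `annual_stocks` (type x year matrix,
#'   Pg C) and `years`.
#' @export
carbon_account <- function(density_stack, landuse, emissions = NULL,
                           pixel_area_ha = 25, emissions_window = 2002:2015,
                           sink_method = c("endpoint", "ols_slope")) {
  sink_method <- match.arg(sink_method)
  dens <- density_stack$density
  years <- density_stack$years
  stopifnot(length(dim(dens)) == 3L, dim(dens)[1] == length(years),
            identical(dim(dens)[2:3], dim(landuse)))
  if (all(is.na(landuse)))
    stop("land-use map has no labelled pixels", call. = FALSE)
  ny <- length(years)
  stocks <- matrix(0, nrow = 8L, ncol = ny,
                   dimnames = list(archetype_names(), years))
  counts <- integer(8)
  for (ty in 1:8) {
    m <- !is.na(landuse) & landuse == ty
    counts[ty] <- sum(m)
    if (counts[ty] > 0)
      for (iy in seq_len(ny))
        stocks[ty, iy] <- stock(dens[iy, , ], m, pixel_area_ha)
  }
  net_sink_of <- function(s) {
    if (sink_method == "endpoint") (s[ny] - s[1]) / (ny - 1)
    else unname(coef(lm(s ~ years))[2])
  }
  deltas <- stocks[, -1, drop = FALSE] - stocks[, -ny, drop = FALSE]
  gross_gain <- rowSums(pmax(deltas, 0))
  gross_loss <- rowSums(pmax(-deltas, 0))
  net_sink <- apply(stocks, 1, net_sink_of)
  mean_density <- vapply(1:8, function(ty) {
    m <- !is.na(landuse) & landuse == ty
    if (!any(m)) return(NA_real_)
    mean(vapply(seq_len(ny), function(iy) mean(dens[iy, , ][m]), numeric(1)))
  }, numeric(1))
  contrib <- net_sink / sum(net_sink) * 100
  offs <- if (!is.null(emissions))
    offset_fraction(net_sink, emissions, emissions_window)
  else rep(NA_real_, 8)
  by_type <- data.frame(
    type = archetype_names(), code = 1:8, n_pixels = counts,
    area_fraction = counts / sum(counts),
    stock_start = stocks[, 1], stock_end = stocks[, ny],
    gross_gain = gross_gain, gross_loss = gross_loss,
    net_sink = net_sink, mean_density = mean_density,
    contribution = contrib,
    contribution_rounded = round_contribution(contrib),
    offset_fraction = offs, row.names = NULL)
  reg_stocks <- unname(colSums(stocks))
  regional <- list(
    stock_start = reg_stocks[1], stock_end = reg_stocks[ny],
    gross_gain = sum(pmax(diff(reg_stocks), 0)),
    gross_loss = sum(pmax(-diff(reg_stocks), 0)),
    net_sink = net_sink_of(reg_stocks),
    offset_fraction = if (!is.null(emissions))
      offset_fraction(net_sink_of(reg_stocks), emissions, emissions_window)
    else NA_real_)
  structure(list(by_type = by_type, regional = regional,
                 annual_stocks = stocks, years = years,
                 sink_method = sink_method),
            class = "carbon_account")
}
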