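## Synthetic landscapes with known ground truth: per-pixel annual
## forest-probability trajectories drawn from eight land-use archetypes,
## a benchmark carbon-density field, coarse-grid microwave series and
## province-level emissions/timber tables.

#' Names of the eight land-use archetypes
#'
#' Dense forest, persistent forest and persistent non-forest are stable
#' types; recovery (slow gain), afforestation (fast plantation),
#' deforestation (loss without regrowth), rotation (cyclic plant/harvest)
#' and rotation_L (large-scale harvest with regrowth staying below the
#' forest state) are change types.
#'
#' @return character vector of length 8, in code order 1..8.
#' @export
archetype_names <- function() {
  c("dense_forest", "forest", "non_forest", "recovery",
    "afforestation", "deforestation", "rotation", "rotation_L")
}

# Default template controls. Probability levels: 0.2 non-forest,
# 0.65 forest, 0.9 dense forest. Change durations: recovery 10 yr
# (slow gain), afforestation 1 yr (a 3-yr change can never reach a
# managed-forest index of 0.4 since |dp|/dt <= 1/3), deforestation 4 yr,
# rotation growth cycle 5 yr with 1-yr clear-cut harvests.
default_archetype_params <- function(archetype) {
  switch(archetype,
    dense_forest  = list(level = 0.9),
    forest        = list(level = 0.65),
    non_forest    = list(level = 0.2),
    recovery      = list(start = 0.2, end = 0.65, onset = 2004, duration = 10),
    afforestation = list(start = 0.2, end = 0.9, onset = 2007, duration = 1),
    deforestation = list(start = 0.65, end = 0.2, onset = 2006, duration = 4),
    rotation      = list(low = 0.2, high = 0.9, cycle = 5),
    rotation_L    = list(pre_level = 0.8, harvest_year = 2007, floor = 0.05,
                         regrow_year = 2010, regrow_level = 0.48),
    stop("unknown archetype: ", archetype, call. = FALSE)
  )
}

#' Specify a synthetic trajectory scenario
#'
#' @param archetype one of [archetype_names()].
#' @param years ordered calendar years (default 2002:2017).
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   probability; generated values are clipped to \[0, 1\].
#' @param params named list overriding the archetype's template controls
#'   (levels, change onset/duration, rotation cycle length, ...).
#' @param seed integer seed or NULL.
#' @return an object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(archetype, years = 2002:2017, noise_sd = 0,
                          params = list(), seed = NULL) {
  if (!is.character(archetype) || length(archetype) != 1L ||
      !(archetype %in% archetype_names()))
    stop("unknown archetype: ", paste(archetype, collapse = ", "),
         call. = FALSE)
  stopifnot(length(years) >= 4L, !is.unsorted(years, strictly = TRUE),
            is.numeric(noise_sd), noise_sd >= 0)
  p <- utils::modifyList(default_archetype_params(archetype), params)
  if (!is.null(p$cycle) && p$cycle < 2)
    stop("rotation cycle length must be >= 2 years", call. = FALSE)
  for (f in c("onset", "harvest_year"))
    if (!is.null(p[[f]]) && (p[[f]] < years[1] || p[[f]] > years[length(years)]))
      stop(f, " must lie within the year range", call. = FALSE)
  structure(list(archetype = archetype, years = years, noise_sd = noise_sd,
                 params = p, seed = seed),
            class = "scenario_spec")
}

# Noise-free archetype template evaluated at the given years.
archetype_template <- function(archetype, years, p) {
  y0 <- years[1]
  ramp <- function(start, end, onset, duration) {
    v <- ifelse(years <= onset, start,
                ifelse(years >= onset + duration, end,
                       start + (end - start) * (years - onset) / duration))
    v
  }
  switch(archetype,
    dense_forest  = rep(p$level, length(years)),
    forest        = rep(p$level, length(years)),
    non_forest    = rep(p$level, length(years)),
    recovery      = ramp(p$start, p$end, p$onset, p$duration),
    afforestation = ramp(p$start, p$end, p$onset, p$duration),
    deforestation = ramp(p$start, p$end, p$onset, p$duration),
    rotation      = {
      # grow low -> high over `cycle` years, clear-cut to low in 1 year
      phase <- (years - y0) %% (p$cycle + 1)
      p$low + (p$high - p$low) * phase / p$cycle
    },
    rotation_L    = {
      v <- rep(p$pre_level, length(years))
      v[years > p$harvest_year] <- p$floor
      v[years > p$regrow_year] <- p$regrow_level
      v
    }
  )
}

#' Generate one annual forest-probability trajectory
#'
#' The noise-free core of each archetype satisfies its defining
#' trajectory (e.g. dense forest stays >= 0.8; afforestation crosses 0.5
#' in a single year; rotation alternates across 0.5 with the requested
#' cycle length). Gaussian noise is added and the result clipped to
#' \[0, 1\].
#'
#' @param spec a [scenario_spec()].
#' @return numeric vector of probabilities named by calendar year.
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  core <- archetype_template(spec$archetype, spec$years, spec$params)
  noise <- if (spec$noise_sd > 0) {
    with_seed(spec$seed, rnorm(length(core), 0, spec$noise_sd))
  } else rep(0, length(core))
  out <- clamp01(core + noise)
  names(out) <- spec$years
  out
}

#' Generate a synthetic scene stack
#'
#' Builds a year x row x col probability array whose pixels follow the
#' requested archetype layout, plus the ground-truth label map. Pixels
#' are laid out row-major in layout order on a grid whose dimensions
#' factor the total pixel count.
#'
#' @param layout named integer vector mapping archetype to pixel count.
#' @param years calendar years (default 2002:2017).
#' @param noise_sd per-observation Gaussian probability noise.
#' @param seed integer seed.
#' @param params optional named list of per-archetype parameter overrides
#'   (list of lists keyed by archetype).
#' @return an object of class `"scene_stack"` with elements
#'   `probability` (year x row x col), `truth_labels` (row x col integer
#'   matrix with a `levels` attribute), `years`, `pixel_area_ha` (25).
#' @export
generate_scene <- function(layout, years = 2002:2017, noise_sd = 0,
                           seed = 1L, params = list()) {
  if (length(layout) == 0L || sum(layout) <= 0)
    stop("layout must request at least one pixel", call. = FALSE)
  bad <- setdiff(names(layout), archetype_names())
  if (length(bad)) stop("unknown archetype: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  layout <- layout[layout > 0]
  total <- sum(layout)
  # most square factorisation of the pixel count
  divs <- which(total %% seq_len(floor(sqrt(total))) == 0)
  nrow_ <- max(divs)
  ncol_ <- total %/% nrow_
  labels <- rep(match(names(layout), archetype_names()), times = layout)
  truth <- matrix(labels, nrow = nrow_, ncol = ncol_, byrow = TRUE)
  attr(truth, "levels") <- archetype_names()
  ny <- length(years)
  prob <- array(NA_real_, dim = c(ny, nrow_, ncol_))
  with_seed(seed, {
    for (r in seq_len(nrow_)) for (cc in seq_len(ncol_)) {
      a <- archetype_names()[truth[r, cc]]
      sp <- scenario_spec(a, years, noise_sd = 0,
                          params = params[[a]] %||% list())
      core <- archetype_template(sp$archetype, years, sp$params)
      e <- if (noise_sd > 0) rnorm(ny, 0, noise_sd) else 0
      prob[, r, cc] <- clamp01(core + e)
    }
  })
  structure(list(probability = prob, truth_labels = truth, years = years,
                 pixel_area_ha = 25, noise_sd = noise_sd, seed = seed),
            class = "scene_stack")
}

#' Default probability-to-carbon-density law
#'
#' Linear law calibrated so dense-forest pixels (p = 0.9) sit near
#' 105 Mg C/ha, persistent forest (p = 0.65) near 75 and persistent
#' non-forest (p = 0.2) near 22, floored at zero.
#'
#' @param p forest probability in \[0, 1\].
#' @return carbon density, Mg C per hectare.
#' @export
default_density_law <- function(p) pmax(0, 118 * p - 1.6)

#' Generate a benchmark carbon-density raster for a scene
#'
#' Applies a monotone probability-to-density law to the scene's
#' probability field in the benchmark year and adds optional Gaussian
#' noise (floored at 0). Stands in for a single-date biomass benchmark
#' map.
#'
#' @param stack a [generate_scene()] result.
#' @param density_law monotone non-decreasing function \[0,1\] -> Mg C/ha.
#' @param noise_sd density noise standard deviation (Mg C/ha).
#' @param seed integer seed.
#' @param year benchmark year (default 2015 if present, else last year).
#' @return row x col matrix of densities (Mg C/ha), with attribute
#'   `"year"`.
#' @export
generate_cdensity_benchmark <- function(stack, density_law = default_density_law,
                                        noise_sd = 0, seed = 1L, year = NULL) {
  stopifnot(inherits(stack, "scene_stack"))
  grid <- seq(0, 1, by = 0.01)
  vals <- density_law(grid)
  if (any(diff(vals) < -1e-9))
    stop("density_law must be monotone non-decreasing on [0, 1]",
         call. = FALSE)
  year <- year %||% (if (2015 %in% stack$years) 2015 else max(stack$years))
  iy <- match(year, stack$years)
  if (is.na(iy)) stop("benchmark year not in scene years", call. = FALSE)
  p <- stack$probability[iy, , ]
  dens <- density_law(p)
  if (noise_sd > 0)
    dens <- dens + with_seed(seed, rnorm(length(dens), 0, noise_sd))
  dens <- pmax(0, dens)
  dens <- matrix(dens, nrow = dim(stack$probability)[2])
  attr(dens, "year") <- year
  dens
}

# Fixed monotone band responses to forest probability (7 reflectance
# bands). Chosen invertible so classifier/regressor recovery tests have
# a learnable noise-free limit.
band_response <- function(p, band) {
  switch(band,
         0.08 - 0.050 * p,
         0.25 + 0.200 * p,
         0.10 - 0.060 * p,
         0.12 + 0.100 * p,
         0.22 - 0.100 * p,
         0.18 - 0.120 * p,
         0.15 - 0.090 * p)
}

#' Attach synthetic reflectance and elevation to a scene
#'
#' Seven reflectance bands are fixed monotone functions of the pixel's
#' forest probability plus Gaussian noise; elevation is an independent
#' uniform field (m).
#'
#' @param stack a [generate_scene()] result.
#' @param noise_sd reflectance noise standard deviation.
#' @param seed integer seed.
#' @return the stack with `reflectance` (year x band x row x col) and
#'   `elevation` (row x col) added.
#' @export
add_reflectance <- function(stack, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(stack, "scene_stack"))
  d <- dim(stack$probability)
  refl <- array(NA_real_, dim = c(d[1], 7L, d[2], d[3]))
  with_seed(seed, {
    for (b in 1:7) {
      base <- band_response(stack$probability, b)
      e <- if (noise_sd > 0) rnorm(length(base), 0, noise_sd) else 0
      refl[, b, , ] <- base + e
    }
    stack$elevation <- matrix(runif(d[2] * d[3], 100, 1500), d[2], d[3])
  })
  stack$reflectance <- refl
  stack
}

#' Specify a synthetic coarse-grid microwave series
#'
#' @param n_cells number of 25 x 25 km cells.
#' @param dates observation dates (Date), strictly increasing; default
#'   every third day 2010-2017.
#' @param sm_trend imposed soil-moisture slope(s), m3/m3 per year;
#'   scalar or length `n_cells`.
#' @param vod_trend imposed VOD slope(s) per year.
#' @param obs_noise_sd named vector with elements `vod` and `sm`.
#' @param tbrmse_distribution function(n) sampling per-observation
#'   TB-RMSE values (K).
#' @param flag_rates named probabilities for `frozen`, `topography`,
#'   `urban`, `water` flags.
#' @param seed integer seed.
#' @return an object of class `"coarse_series_spec"`.
#' @export
coarse_series_spec <- function(n_cells,
                               dates = seq(as.Date("2010-01-01"),
                                           as.Date("2017-12-31"), by = 3),
                               sm_trend = 0, vod_trend = 0,
                               obs_noise_sd = c(vod = 0.02, sm = 0.015),
                               tbrmse_distribution = function(n)
                                 stats::rgamma(n, shape = 2, scale = 3),
                               flag_rates = c(frozen = 0.02, topography = 0.01,
                                              urban = 0.01, water = 0.01),
                               seed = 1L) {
  if (length(dates) == 0L) stop("no dates supplied", call. = FALSE)
  stopifnot(n_cells >= 1L, !is.unsorted(as.numeric(dates), strictly = TRUE))
  if (any(flag_rates < 0 | flag_rates > 1))
    stop("flag rates must lie in [0, 1]", call. = FALSE)
  rec <- function(x) if (length(x) == 1L) rep(x, n_cells) else x
  sm_trend <- rec(sm_trend); vod_trend <- rec(vod_trend)
  stopifnot(length(sm_trend) == n_cells, length(vod_trend) == n_cells)
  structure(list(n_cells = n_cells, dates = as.Date(dates),
                 sm_trend = sm_trend, vod_trend = vod_trend,
                 obs_noise_sd = obs_noise_sd,
                 tbrmse_distribution = tbrmse_distribution,
                 flag_rates = flag_rates, seed = seed),
            class = "coarse_series_spec")
}

#' Generate coarse-grid microwave observation streams
#'
#' Emits dated VOD / soil-moisture / soil-temperature / TB-RMSE records
#' for ascending and descending orbits per cell, with imposed linear
#' trends, mild seasonality, observation noise and random quality flags,
#' plus the ground-truth trends for recovery tests.
#'
#' @param spec a [coarse_series_spec()].
#' @return list with `records` (data.frame: cell, date, orbit, vod, sm,
#'   soil_temp, tb_rmse, flag_frozen, flag_topography, flag_urban,
#'   flag_water) and `truth` (data.frame: cell, sm_trend, vod_trend).
#' @export
generate_coarse_series <- function(spec) {
  stopifnot(inherits(spec, "coarse_series_spec"))
  dates <- spec$dates
  nd <- length(dates)
  t_yr <- as.numeric(dates - as.Date("2010-01-01")) / 365.25
  doy <- as.integer(format(dates, "%j"))
  season_v <- 0.03 * sin(2 * pi * (doy - 200) / 365)
  temp_base <- 284 + 12 * sin(2 * pi * (doy - 120) / 365)
  orbits <- c("ascending", "descending")
  out <- with_seed(spec$seed, {
    rows <- vector("list", spec$n_cells * 2L)
    k <- 0L
    for (cell in seq_len(spec$n_cells)) {
      vod0 <- 0.45; sm0 <- 0.25
      for (orb in orbits) {
        nz <- spec$obs_noise_sd
        vod <- vod0 + spec$vod_trend[cell] * t_yr + season_v +
          (if (nz[["vod"]] > 0) rnorm(nd, 0, nz[["vod"]]) else 0)
        sm <- clamp01(sm0 + spec$sm_trend[cell] * t_yr +
                        (if (nz[["sm"]] > 0) rnorm(nd, 0, nz[["sm"]]) else 0))
        fr <- spec$flag_rates
        k <- k + 1L
        rows[[k]] <- data.frame(
          cell = cell, date = dates, orbit = orb, vod = vod, sm = sm,
          soil_temp = temp_base + rnorm(nd, 0, 1.5),
          tb_rmse = spec$tbrmse_distribution(nd),
          flag_frozen = runif(nd) < fr[["frozen"]],
          flag_topography = runif(nd) < fr[["topography"]],
          flag_urban = runif(nd) < fr[["urban"]],
          flag_water = runif(nd) < fr[["water"]])
      }
    }
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  list(records = out,
       truth = data.frame(cell = seq_len(spec$n_cells),
                          sm_trend = spec$sm_trend,
                          vod_trend = spec$vod_trend))
}

#' Generate province-level emissions and timber tables
#'
#' The regional fossil-carbon emission series follows a
#' rise-then-plateau shape anchored at 0.21 Pg C in 1997 rising
#' linearly to a 0.63 Pg C plateau in 2012; the regional timber-carbon
#' equivalent ramps linearly from 0.004 Pg C (2003) to 0.012 Pg C
#' (2017). Province shares are random but renormalised each year so the
#' regional series passes through the anchors exactly; only the share
#' noise depends on the seed.
#'
#' @param n_provinces number of provinces (default 8).
#' @param years emission years (default 1997:2015).
#' @param timber_years timber years (default 2002:2017).
#' @param emissions_shape `"rise_then_plateau"` or a function(years) of
#'   regional Pg C values.
#' @param timber_shape `"linear"`, a constant volume (m3), or a
#'   function(years) of regional timber volumes (m3).
#' @param wood_density wood basic density used to express the timber
#'   ramp in carbon units, Mg per m3.
#' @param share_noise_sd multiplicative log-normal sd on province shares.
#' @param seed integer seed.
#' @return list of data.frames `emissions` (province, year, value,
#'   units = "PgC") and `timber` (province, year, volume in m3).
#' @export
generate_province_tables <- function(n_provinces = 8L, years = 1997:2015,
                                     timber_years = 2002:2017,
                                     emissions_shape = "rise_then_plateau",
                                     timber_shape = "linear",
                                     wood_density = 0.45,
                                     share_noise_sd = 0.1, seed = 1L) {
  if (length(years) == 0L) stop("years must be non-empty", call. = FALSE)
  regional_emis <- if (is.function(emissions_shape)) {
    emissions_shape(years)
  } else if (identical(emissions_shape, "rise_then_plateau")) {
    pmin(0.63, 0.21 + (0.63 - 0.21) * (years - 1997) / (2012 - 1997))
  } else stop("unknown emissions_shape", call. = FALSE)
  regional_vol <- if (is.function(timber_shape)) {
    timber_shape(timber_years)
  } else if (identical(timber_shape, "linear")) {
    carbon <- 0.004 + (0.012 - 0.004) * (timber_years - 2003) / (2017 - 2003)
    carbon / (wood_density * 0.5) * 1e9
  } else if (is.numeric(timber_shape)) {
    rep(timber_shape, length(timber_years))
  } else stop("unknown timber_shape", call. = FALSE)
  split_region <- function(total, yrs) {
    base <- rep(1 / n_provinces, n_provinces)
    rows <- lapply(seq_along(yrs), function(i) {
      w <- base * exp(rnorm(n_provinces, 0, share_noise_sd))
      w <- w / sum(w)
      data.frame(province = paste0("P", seq_len(n_provinces)),
                 year = yrs[i], value = total[i] * w)
    })
    do.call(rbind, rows)
  }
  with_seed(seed, {
    emis <- split_region(regional_emis, years)
    emis$units <- "PgC"
    timb <- split_region(regional_vol, timber_years)
    names(timb)[names(timb) == "value"] <- "volume"
    list(emissions = emis, timber = timb)
  })
}
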