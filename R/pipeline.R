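## Configuration, orchestration and plain-text I/O binding the stages
## into reproducible runs.

#' Default pipeline configuration
#'
#' Per-stage blocks mirroring the method's printed constants:
#' probability thresholds (dense 0.8, forest 0.5), disturbance-index
#' threshold 0.4 and bins, segmentation (max 6 segments, F-test alpha
#' 0.05), carbon-model split 0.5 with the 2002-2015 emission window,
#' and the microwave filters (TB-RMSE 10 K, 30-day window, 30 kept per
#' year, 10th/90th percentiles).
#'
#' @param ... named overrides for top-level blocks (partial lists are
#'   merged).
#' @return a validated config list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    scene = list(
      layout = c(dense_forest = 88, forest = 205, non_forest = 438,
                 recovery = 54, afforestation = 74, deforestation = 16,
                 rotation = 106, rotation_L = 19),
      years = 2002:2017, noise_sd = 0.02),
    thresholds = list(theta_dense = 0.8, theta_forest = 0.5,
                      disturbance = 0.4, rotation_l = 0.6,
                      bins = c(0.2, 0.4, 0.6)),
    segmentation = list(max_segments = 6L, alpha = 0.05),
    carbon = list(split = 0.5, sink_method = "endpoint",
                  emissions_window = 2002:2015,
                  benchmark_noise_sd = 5, n_rounds = 200L),
    microwave = list(n_cells = 100L, tb_rmse_max = 10, window_days = 30,
                     keep_per_year = 30L, percentiles = c(0.1, 0.9),
                     alpha = 0.05, decline_fraction = 0.08,
                     decline_trend = -0.012),
    wood_density = 0.45)
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Every threshold is checked against its documented domain before any
#' stage runs; an out-of-domain constant aborts with the offending
#' field.
#'
#' @param cfg a config list.
#' @return the config, invisibly; stops on the first violation.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg,
                                         call. = FALSE)
  th <- cfg$thresholds
  chk(th$theta_forest > 0 && th$theta_forest < 1, "theta_forest not in (0,1)")
  chk(th$theta_dense > th$theta_forest && th$theta_dense <= 1,
      "theta_dense must lie in (theta_forest, 1]")
  chk(th$disturbance > 0 && th$disturbance <= 1, "disturbance not in (0,1]")
  chk(!is.unsorted(th$bins) && all(th$bins > 0 & th$bins < 1),
      "index bins must be increasing within (0,1)")
  sg <- cfg$segmentation
  chk(sg$alpha > 0 && sg$alpha <= 1, "alpha not in (0,1]")
  chk(sg$max_segments >= 1 && sg$max_segments <= 10, "max_segments out of range")
  cb <- cfg$carbon
  chk(cb$split > 0 && cb$split < 1, "carbon split not in (0,1)")
  chk(cb$sink_method %in% c("endpoint", "ols_slope"), "unknown sink_method")
  mw <- cfg$microwave
  chk(mw$tb_rmse_max > 0, "tb_rmse_max must be positive")
  chk(mw$window_days >= 1, "window_days must be >= 1")
  chk(mw$keep_per_year >= 1, "keep_per_year must be >= 1")
  chk(all(mw$percentiles >= 0 & mw$percentiles <= 1) &&
        mw$percentiles[1] < mw$percentiles[2], "percentiles invalid")
  chk(mw$alpha > 0 && mw$alpha < 1, "microwave alpha not in (0,1)")
  chk(cfg$wood_density > 0, "wood_density must be positive")
  chk(length(cfg$scene$years) >= 4, "need at least 4 scene years")
  chk(cfg$scene$noise_sd >= 0, "scene noise_sd must be >= 0")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Configs round-trip losslessly through serialization.
#'
#' @param path YAML file path.
#' @param cfg a [pipeline_config()].
#' @return `read_config`: the validated config; `write_config`: the
#'   path, invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$scene$layout <- unlist(raw$scene$layout)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$scene$layout <- as.list(out$scene$layout)  # keep archetype names
  yaml::write_yaml(out, path)
  invisible(path)
}

write_labels_csv <- function(labels, path) {
  idx <- which(!is.na(labels), arr.ind = TRUE)
  df <- data.frame(row = idx[, 1], col = idx[, 2],
                   code = labels[!is.na(labels)])
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(codes = setNames(as.list(1:8), archetype_names()),
         nrow = nrow(labels), ncol = ncol(labels)),
    sub("\\.csv$", "_codes.json", path), auto_unbox = TRUE)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order -- synthetic scene,
#' forest-probability classification, land-use typology, carbon-density
#' model and accounting, microwave filtering and trends, report tables
#' -- and writes every artifact plus a manifest (config hash, seed,
#' package version, per-stage runtimes) into `out_dir`.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return the report bundle, invisibly, with attribute `"manifest"`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("run")) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = digest::digest(unclass(cfg)),
                   seed = cfg$seed,
                   package_version = as.character(utils::packageVersion(
                     "landcarbon")),
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list())
  timer <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed [E_", toupper(name), "]: ",
           conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- round(proc.time()[3] - t0, 3)
    res
  }

  scene <- timer("simulate", {
    s <- generate_scene(cfg$scene$layout, cfg$scene$years,
                        cfg$scene$noise_sd, seed = cfg$seed)
    add_reflectance(s, noise_sd = 0.005, seed = cfg$seed + 1L)
  })
  bench <- timer("benchmark", generate_cdensity_benchmark(
    scene, noise_sd = cfg$carbon$benchmark_noise_sd, seed = cfg$seed + 2L))
  tables <- timer("provinces", generate_province_tables(
    seed = cfg$seed + 3L, wood_density = cfg$wood_density))

  typo_cfg <- typology_config(
    theta_dense = cfg$thresholds$theta_dense,
    theta_forest = cfg$thresholds$theta_forest,
    disturbance = cfg$thresholds$disturbance,
    rotation_l = cfg$thresholds$rotation_l, bins = cfg$thresholds$bins,
    alpha = cfg$segmentation$alpha,
    max_segments = cfg$segmentation$max_segments)
  cls <- timer("typology", classify_scene(scene, typo_cfg,
                                          diagnostics = TRUE))

  account <- timer("carbon", {
    by <- attr(bench, "year")
    iy <- match(by, scene$years)
    preds <- c(lapply(1:7, function(b) {
      matrix(scene$reflectance[iy, b, , ], dim(bench)[1])
    }), list(scene$elevation))
    names(preds) <- c(paste0("band_", 1:7), "elevation")
    cmod <- train_cdensity_model(bench, preds, split = cfg$carbon$split,
                                 seed = cfg$seed + 4L,
                                 n_rounds = cfg$carbon$n_rounds)
    dens <- array(NA_real_, dim = dim(scene$probability))
    for (k in seq_along(scene$years)) {
      pk <- c(lapply(1:7, function(b)
        matrix(scene$reflectance[k, b, , ], dim(bench)[1])),
        list(scene$elevation))
      names(pk) <- names(preds)
      dens[k, , ] <- predict_cdensity(cmod, pk)
    }
    acc <- carbon_account(list(density = dens, years = scene$years),
                          cls$labels, tables$emissions,
                          pixel_area_ha = scene$pixel_area_ha,
                          emissions_window = cfg$carbon$emissions_window,
                          sink_method = cfg$carbon$sink_method)
    acc$model_quality <- cmod$quality
    acc
  })

  trends <- timer("microwave", {
    mw <- cfg$microwave
    n_decline <- round(mw$decline_fraction * mw$n_cells)
    sm_tr <- c(rep(mw$decline_trend, n_decline),
               rep(0, mw$n_cells - n_decline))
    cs <- generate_coarse_series(coarse_series_spec(
      mw$n_cells, sm_trend = sm_tr, seed = cfg$seed + 5L))
    filt <- quality_filter(cs$records, mw$tb_rmse_max)
    cell_trends(annualize(filt, "sm"), alpha = mw$alpha)
  })

  report <- timer("report", {
    dist_years <- with(cls$diagnostics, rep(NA_integer_, 0))
    summary_tables(account, trends = trends, timber = tables$timber,
                   wood_density = cfg$wood_density)
  })

  utils::write.csv(report$type_table, file.path(out_dir, "type_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$flux_table, file.path(out_dir, "flux_table.csv"),
                   row.names = FALSE)
  utils::write.csv(trends$trends, file.path(out_dir, "sm_trends.csv"),
                   row.names = FALSE)
  utils::write.csv(tables$emissions, file.path(out_dir, "emissions.csv"),
                   row.names = FALSE)
  write_labels_csv(cls$labels, file.path(out_dir, "landuse_labels.csv"))
  jsonlite::write_json(account$regional, file.path(out_dir, "regional.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  attr(report, "manifest") <- manifest
  attr(report, "account") <- account
  attr(report, "classification") <- cls
  invisible(report)
}
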