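## Cross-product comparison (block aggregation, correlation,
## RMSE-as-uncertainty) and report-table generation.

#' Aggregate a fine raster into coarse blocks
#'
#' Each coarse cell is the mean over the valid fine cells of its
#' `factor` x `factor` block. Trailing rows/columns not filling a block
#' are dropped (count attached as attribute `"n_dropped"`). With
#' complete blocks and no missing data the global mean is preserved.
#'
#' @param x numeric matrix.
#' @param factor integer block edge length (>= 1).
#' @return coarse matrix of block means.
#' @export
block_aggregate <- function(x, factor) {
  if (factor < 1) stop("factor must be >= 1", call. = FALSE)
  factor <- as.integer(factor)
  nr <- (nrow(x) %/% factor) * factor
  nc <- (ncol(x) %/% factor) * factor
  dropped <- length(x) - nr * nc
  x <- x[seq_len(nr), seq_len(nc), drop = FALSE]
  ri <- (seq_len(nr) - 1L) %/% factor
  ci <- (seq_len(nc) - 1L) %/% factor
  grp <- outer(ri, ci, function(a, b) a + b * (nr %/% factor)) + 1L
  sums <- tapply(as.numeric(x), as.numeric(grp), mean, na.rm = TRUE)
  out <- matrix(as.numeric(sums), nr %/% factor, nc %/% factor)
  out[is.nan(out)] <- NA_real_
  attr(out, "n_dropped") <- dropped
  out
}

#' Compare two aligned products
#'
#' Pearson correlation (Spearman via `method`) and RMSE over paired
#' valid cells or time steps, complete cases only. Symmetric in both
#' statistics.
#'
#' @param a,b aligned numeric vectors/matrices (same length).
#' @param method correlation estimator (default `"pearson"`).
#' @return list with `r`, `rmse`, `n`.
#' @export
compare_products <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) stop("need at least 3 paired values", call. = FALSE)
  list(r = cor(a[ok], b[ok], method = method),
       rmse = sqrt(mean((a[ok] - b[ok])^2)),
       n = sum(ok))
}

#' Build the summary report bundle
#'
#' Produces the per-type accounting table (area share, mean density,
#' net sink, contribution), the gross-flux decomposition, an optional
#' timber-versus-net-sink series and an optional disturbance-timing
#' histogram. Pure: identical inputs give byte-identical tables.
#'
#' @param account a [carbon_account()] result.
#' @param trends optional [cell_trends()] result.
#' @param timber optional data.frame with `year` and `volume` (m3),
#'   e.g. aggregated from [generate_province_tables()].
#' @param disturbance_years optional vector of per-disturbance calendar
#'   years (from segmentation vertices) to histogram.
#' @param wood_density wood basic density for timber conversion.
#' @return named list of data.frames: `type_table`, `flux_table`, and
#'   when inputs are given `timber_series`, `disturbance_histogram`,
#'   `trend_summary`.
#' @export
summary_tables <- function(account, trends = NULL, timber = NULL,
                           disturbance_years = NULL, wood_density = 0.45) {
  stopifnot(inherits(account, "carbon_account"))
  bt <- account$by_type
  type_table <- data.frame(
    type = bt$type,
    area_pct = round(bt$area_fraction * 100, 1),
    mean_density = round(bt$mean_density, 1),
    net_sink = bt$net_sink,
    contribution_pct = bt$contribution_rounded,
    offset_pct = round_contribution(bt$offset_fraction))
  flux_table <- data.frame(
    type = bt$type,
    stock_2002 = bt$stock_start,
    gross_gain = bt$gross_gain,
    gross_loss = bt$gross_loss,
    net_change = bt$gross_gain - bt$gross_loss)
  out <- list(type_table = type_table, flux_table = flux_table)
  if (!is.null(timber)) {
    vol <- tapply(timber$volume, timber$year, sum)
    out$timber_series <- data.frame(
      year = as.integer(names(vol)),
      volume = as.numeric(vol),
      carbon = timber_carbon(as.numeric(vol), wood_density))
  }
  if (!is.null(disturbance_years) && length(disturbance_years)) {
    tb <- table(disturbance_years)
    out$disturbance_histogram <- data.frame(
      year = as.integer(names(tb)),
      count = as.integer(tb),
      fraction = as.integer(tb) / length(disturbance_years))
  }
  if (!is.null(trends)) {
    out$trend_summary <- data.frame(
      n_cells = trends$summary$n_cells,
      n_masked = trends$summary$n_masked,
      significant_decline_fraction =
        trends$summary$significant_decline_fraction)
  }
  out
}
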