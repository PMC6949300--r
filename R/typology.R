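## Managed-forest disturbance indices, the nine forest-dynamics classes
## and the eight final land-use types.

#' Default typology thresholds
#'
#' @param theta_dense dense-forest probability threshold (0.8).
#' @param theta_forest forest/non-forest probability threshold (0.5).
#' @param disturbance index value at or above which a segment counts as
#'   a major (human) disturbance (0.4).
#' @param rotation_l decrease-index value above which a forest-to-
#'   non-forest trajectory with regrowth is labelled rotation_L (0.6).
#' @param bins upper edges of the very_low/low/intermediate index bins.
#' @param alpha segmentation F-test level.
#' @param max_segments segmentation segment cap.
#' @return named list of thresholds.
#' @export
typology_config <- function(theta_dense = 0.8, theta_forest = 0.5,
                            disturbance = 0.4, rotation_l = 0.6,
                            bins = c(0.2, 0.4, 0.6), alpha = 0.05,
                            max_segments = 6L) {
  stopifnot(theta_dense > theta_forest, theta_forest > 0,
            disturbance > 0, disturbance <= 1,
            length(bins) == 3L, !is.unsorted(bins))
  list(theta_dense = theta_dense, theta_forest = theta_forest,
       disturbance = disturbance, rotation_l = rotation_l, bins = bins,
       alpha = alpha, max_segments = as.integer(max_segments))
}

index_category <- function(x, bins = c(0.2, 0.4, 0.6)) {
  cats <- c("very_low", "low", "intermediate", "high")
  cats[findInterval(x, c(-Inf, bins)) ]
}

#' Managed-forest increase and decrease indices
#'
#' The increase (decrease) index is the largest magnitude-to-duration
#' ratio over segments with positive (negative) magnitude, i.e. the
#' velocity of the strongest gain (loss); 0 when no such segment exists.
#' Values near 1 mean a full forest/non-forest transition within a year
#' (rapid plantation or clear-cut); values near 0 mean slow change.
#' Bins are left-closed: \[0, 0.2) very_low, \[0.2, 0.4) low,
#' \[0.4, 0.6) intermediate, \[0.6, 1\] high.
#'
#' @param result a [segment_series()] result.
#' @param bins bin edges (see [typology_config()]).
#' @return list with `increase_index`, `decrease_index`,
#'   `increase_category`, `decrease_category`.
#' @export
disturbance_indices <- function(result, bins = c(0.2, 0.4, 0.6)) {
  stopifnot(inherits(result, "segmentation_result"))
  seg <- result$segments
  rate <- seg$magnitude / seg$duration
  inc <- if (any(rate > 0)) max(rate[rate > 0]) else 0
  dec <- if (any(rate < 0)) max(-rate[rate < 0]) else 0
  list(increase_index = inc, decrease_index = dec,
       increase_category = index_category(inc, bins),
       decrease_category = index_category(dec, bins))
}

#' Nine-class forest dynamics
#'
#' Classes 1-3 are stable (probability always >= 0.8 dense forest,
#' always >= 0.5 forest, always < 0.5 non-forest). Classes 4-7 cross the
#' forest threshold once between the first and last year: 4/5 upward
#' without/with a major negative disturbance segment, 6/7 downward
#' without/with a major positive disturbance segment. Classes 8/9 cross
#' in both directions and end where they started (8 non-forest, 9
#' forest). A segment is a major disturbance when
#' |magnitude| / duration >= the disturbance threshold.
#'
#' @param series observed probability series.
#' @param result its [segment_series()] result.
#' @param config a [typology_config()].
#' @return integer class code 1..9.
#' @export
dynamics_class <- function(series, result, config = typology_config()) {
  x <- as.numeric(series)
  x <- fill_gaps(x)
  if (is.null(x)) stop("series too gappy to classify", call. = FALSE)
  seg <- result$segments
  rate <- seg$magnitude / seg$duration
  pos_dist <- any(rate >= config$disturbance)
  neg_dist <- any(-rate >= config$disturbance)
  thf <- config$theta_forest
  if (all(x >= config$theta_dense)) return(1L)
  if (all(x >= thf)) return(2L)
  if (all(x < thf)) return(3L)
  s <- x[1] >= thf
  e <- x[length(x)] >= thf
  if (!s && e) return(if (neg_dist) 5L else 4L)
  if (s && !e) return(if (pos_dist) 7L else 6L)
  if (!s && !e) return(8L)
  9L
}

#' Assign the final land-use type
#'
#' Deterministic priority-ordered rule table combining the strongest
#' managed-forest increase, strongest decrease and the dynamics class.
#' Stable dynamics with both indices below the disturbance threshold map
#' to the three persistent types; upward transitions split into recovery
#' (slow) versus afforestation (rapid gain, no major loss); downward
#' transitions without regrowth are deforestation; downward transitions
#' with regrowth and a rapid loss (decrease index > `rotation_l`) are
#' rotation_L; every residual disturbed combination falls back to
#' rotation, the generic managed-change type.
#'
#' @param indices a [disturbance_indices()] result.
#' @param dyn dynamics class code (1..9).
#' @param config a [typology_config()].
#' @return integer type code 1..8 named by the archetype.
#' @export
landuse_type <- function(indices, dyn, config = typology_config()) {
  stopifnot(dyn %in% 1:9)
  inc <- indices$increase_index
  dec <- indices$decrease_index
  thr <- config$disturbance
  calm <- inc < thr && dec < thr
  code <- switch(as.character(dyn),
    "1" = if (calm) 1L else 2L,
    "2" = 2L,
    "3" = 3L,
    "4" = if (inc < thr) 4L else if (dec < thr) 5L else 7L,
    "5" = if (inc >= thr && dec < thr) 5L else 7L,
    "6" = 6L,
    "7" = if (dec > config$rotation_l) 8L else 7L,
    "8" = if (calm) 3L else 7L,
    "9" = if (calm) 2L else 7L)
  setNames(code, archetype_names()[code])
}

#' Classify every pixel of a probability stack
#'
#' Runs segmentation, disturbance indices, dynamics class and the
#' land-use rule table per pixel. Pixels whose series cannot be
#' segmented (too many missing years) are masked. Identical series are
#' classified once (noise-free scenes collapse to a handful of unique
#' trajectories).
#'
#' @param stack a `scene_stack` or a list with `probability`
#'   (year x row x col) and `years`.
#' @param config a [typology_config()].
#' @param diagnostics if TRUE also return per-pixel indices, class and
#'   fit statistics.
#' @return list with `labels` (row x col integer matrix, levels
#'   attribute = [archetype_names()], NA = masked), `summary`
#'   (data.frame: type, code, count, fraction of valid pixels),
#'   `n_masked`, and optionally `diagnostics`.
#' @export
classify_scene <- function(stack, config = typology_config(),
                           diagnostics = FALSE) {
  prob <- stack$probability
  years <- stack$years
  stopifnot(length(dim(prob)) == 3L, dim(prob)[1] == length(years),
            length(years) >= 4L)
  nr <- dim(prob)[2]; nc <- dim(prob)[3]
  ctx <- segmentation_context(years, config$max_segments)
  cache <- new.env(parent = emptyenv())
  labels <- matrix(NA_integer_, nr, nc)
  diag_rows <- if (diagnostics) vector("list", nr * nc) else NULL
  n_masked <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    y <- prob[, r, cc]
    key <- paste(round(y, 10), collapse = ",")
    hit <- cache[[key]]
    if (is.null(hit)) {
      hit <- tryCatch({
        res <- segment_series(y, years, config$max_segments, config$alpha,
                              context = ctx)
        idx <- disturbance_indices(res, config$bins)
        dyn <- dynamics_class(y, res, config)
        type <- landuse_type(idx, dyn, config)
        list(type = type, inc = idx$increase_index,
             dec = idx$decrease_index, dyn = dyn, sse = res$sse,
             k = res$n_segments)
      }, error = function(e) NA)
      cache[[key]] <- hit
    }
    if (length(hit) == 1L && is.na(hit[[1]])) {
      n_masked <- n_masked + 1L
    } else {
      labels[r, cc] <- hit$type
      if (diagnostics)
        diag_rows[[(r - 1L) * nc + cc]] <- data.frame(
          row = r, col = cc, type = unname(hit$type),
          increase_index = hit$inc, decrease_index = hit$dec,
          dynamics = hit$dyn, sse = hit$sse, n_segments = hit$k)
    }
  }
  attr(labels, "levels") <- archetype_names()
  valid <- sum(!is.na(labels))
  counts <- tabulate(labels[!is.na(labels)], nbins = 8L)
  out <- list(labels = labels,
              summary = data.frame(type = archetype_names(),
                                   code = 1:8, count = counts,
                                   fraction = if (valid > 0)
                                     counts / valid else rep(NA_real_, 8)),
              n_masked = n_masked)
  if (diagnostics)
    out$diagnostics <- do.call(rbind, diag_rows[!vapply(diag_rows, is.null,
                                                        logical(1))])
  out
}
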