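## Temporal segmentation of annual forest-probability series into
## continuous piecewise-linear segments (LandTrendr-style): exact
## least-squares fits over all interior-vertex placements, with the
## segment count chosen by an incremental F-test.

# Precompute, for a fixed year grid, the orthonormal bases of every
# candidate vertex placement for every segment count k. The continuous
# piecewise-linear model with interior vertices v_1..v_{k-1} is spanned
# by {1, t, max(0, t - v_j)}; the residual SSE of a series y against a
# placement with orthonormal basis Q is ||y||^2 - ||Q'y||^2, so one
# matrix product scores all placements at once.
segmentation_context <- function(years, max_segments = 6L) {
  n <- length(years)
  stopifnot(n >= 4L, !is.unsorted(years, strictly = TRUE))
  kmax <- min(max_segments, n - 1L)
  interior <- if (n > 2L) seq(2L, n - 1L) else integer(0)
  t0 <- years - years[1]
  per_k <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    placements <- if (k == 1L) {
      matrix(integer(0), nrow = 0, ncol = 1)
    } else {
      combn(interior, k - 1L)  # columns in lexicographic order
    }
    np <- ncol(placements)
    p <- k + 1L
    qs <- vector("list", np)
    for (j in seq_len(np)) {
      X <- cbind(1, t0)
      for (v in placements[, j]) X <- cbind(X, pmax(0, t0 - t0[v]))
      qs[[j]] <- t(qr.Q(qr(X)))
    }
    per_k[[k]] <- list(placements = placements,
                       Q = do.call(rbind, qs),
                       group = rep(seq_len(np), each = p),
                       p = p, np = np)
  }
  structure(list(years = years, n = n, kmax = kmax, per_k = per_k,
                 t0 = t0),
            class = "segmentation_context")
}

# Best (minimum) SSE and earliest-minimising placement index for k
# segments. Ties break toward the earliest (lexicographically first)
# placement because which.min returns the first minimum.
.best_for_k <- function(y, ctx, k) {
  pk <- ctx$per_k[[k]]
  proj <- as.numeric(pk$Q %*% y)
  expl <- rowsum(proj^2, pk$group)
  sse <- sum(y^2) - expl
  sse <- pmax(sse, 0)
  j <- which.min(round(sse, 12))
  list(sse = sse[j], placement = if (k == 1L) integer(0) else
    pk$placements[, j])
}

# Fill short gaps (<= max_gap consecutive NAs) by linear interpolation;
# returns NULL when the series is unusable.
fill_gaps <- function(y, max_gap = 2L) {
  if (!anyNA(y)) return(y)
  ok <- which(!is.na(y))
  if (length(ok) < 4L) return(NULL)
  runs <- rle(is.na(y))
  if (any(runs$values & runs$lengths > max_gap)) return(NULL)
  if (is.na(y[1]) || is.na(y[length(y)])) return(NULL)
  approx(ok, y[ok], xout = seq_along(y))$y
}

#' Segment an annual probability series
#'
#' Fits a continuous piecewise-linear trajectory with up to
#' `max_segments` segments whose interior vertices sit on observation
#' years. For each candidate segment count the vertex placement
#' minimising the residual sum of squares is found exactly (exhaustive
#' search over placements, shared-basis projection); the segment count
#' is the smallest k whose fit is not significantly worse than the
#' richest allowed fit under a partial F-test at level `alpha`, so
#' vertices the data do not demand are dropped (fit-then-simplify, in
#' the manner of LandTrendr). Interior gaps of at
#' most two consecutive missing years are linearly interpolated first.
#'
#' @param series numeric probability series (may carry years as names).
#' @param years calendar years; defaults to `names(series)` or a unit
#'   sequence.
#' @param max_segments maximum number of segments (default 6).
#' @param alpha significance level of the incremental F-test (default
#'   0.05).
#' @param context optional precomputed [segmentation_context()] for
#'   `years` (used by [classify_scene()] to amortise the basis setup).
#' @return an object of class `"segmentation_result"`: a list with
#'   `segments` (data.frame: start_year, end_year, start_value,
#'   end_value, duration, magnitude, direction), `fitted_values`,
#'   `sse`, `n_segments` and `years`.
#' @export
segment_series <- function(series, years = NULL, max_segments = 6L,
                           alpha = 0.05, context = NULL) {
  if (is.null(years)) {
    years <- if (!is.null(names(series))) as.numeric(names(series))
    else seq_along(series)
  }
  stopifnot(length(series) == length(years))
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  y <- fill_gaps(as.numeric(series))
  if (is.null(y) || length(y) < 4L)
    stop("series too short or too gappy to segment (need >= 4 finite ",
         "values, gaps <= 2 years)", call. = FALSE)
  ctx <- context %||% segmentation_context(years, max_segments)
  stopifnot(identical(ctx$years, years))
  n <- ctx$n
  tol0 <- 1e-10 * max(1, sum(y^2))
  # Reference model: the richest fit whose F-test keeps >= 1 residual df.
  kref <- min(ctx$kmax, n - 2L)
  best <- lapply(seq_len(kref), .best_for_k, y = y, ctx = ctx)
  sse <- vapply(best, `[[`, numeric(1), "sse")
  # Smallest k whose fit is not significantly worse than the reference
  # fit (partial F-test); vertices the data do not demand are dropped.
  df2 <- n - (kref + 1L)
  k <- kref
  for (kk in seq_len(kref)) {
    if (sse[kk] <= tol0) { k <- kk; break }
    if (sse[kref] <= tol0) next  # exact richer fit always wins the F-test
    f <- ((sse[kk] - sse[kref]) / (kref - kk + 1e-300)) / (sse[kref] / df2)
    if (kk == kref || pf(f, kref - kk, df2, lower.tail = FALSE) >= alpha) {
      k <- kk; break
    }
  }
  sel <- best[[k]]
  X <- cbind(1, ctx$t0)
  for (v in sel$placement) X <- cbind(X, pmax(0, ctx$t0 - ctx$t0[v]))
  fitv <- as.numeric(X %*% qr.coef(qr(X), y))
  verts <- c(1L, sel$placement, n)
  seg <- data.frame(
    start_year = years[verts[-length(verts)]],
    end_year = years[verts[-1]],
    start_value = fitv[verts[-length(verts)]],
    end_value = fitv[verts[-1]])
  seg$duration <- seg$end_year - seg$start_year
  seg$magnitude <- seg$end_value - seg$start_value
  seg$direction <- sign(seg$magnitude)
  structure(list(segments = seg,
                 fitted_values = setNames(fitv, years),
                 sse = sel$sse, n_segments = k, years = years),
            class = "segmentation_result")
}
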