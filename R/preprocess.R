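## Annual compositing and denoising of reflectance series, and the
## probabilistic forest/non-forest classifier producing annual
## forest-probability maps.

#' Annual median composite of daily reflectance
#'
#' Per pixel and band, the median over valid (non-missing) daily
#' observations within one calendar year; pixels with no valid
#' observation are flagged missing (NA). Even counts use the mean of the
#' two central values. The result is invariant to the order of the daily
#' images.
#'
#' @param daily 4-d array (obs x band x row x col), NA = missing.
#' @param dates Date (or year-coercible) vector, one per observation.
#' @param year calendar year to composite.
#' @return band x row x col array.
#' @export
annual_median_composite <- function(daily, dates, year) {
  stopifnot(length(dim(daily)) == 4L, dim(daily)[1] == length(dates))
  yrs <- if (inherits(dates, "Date")) as.integer(format(dates, "%Y"))
  else as.integer(dates)
  sel <- which(yrs == year)
  if (!length(sel)) stop("year ", year, " absent from input dates",
                         call. = FALSE)
  apply(daily[sel, , , , drop = FALSE], c(2, 3, 4), median, na.rm = TRUE)
}

#' Three-year moving median of an annual series
#'
#' Only full windows are emitted, so the output is shorter than the
#' input. The default `"trailing"` alignment (output year t is the
#' median of years t-2..t) maps a 2000-2017 input to a 2002-2017 output;
#' `"centered"` gives 2001-2016.
#'
#' @param x annual values.
#' @param years calendar years (default `names(x)` or unit sequence).
#' @param alignment `"trailing"` or `"centered"`.
#' @return named numeric vector of smoothed values.
#' @export
moving_median3 <- function(x, years = NULL, alignment = c("trailing",
                                                          "centered")) {
  alignment <- match.arg(alignment)
  n <- length(x)
  if (n < 3L) stop("need at least 3 annual values", call. = FALSE)
  if (is.null(years)) {
    years <- if (!is.null(names(x))) as.numeric(names(x)) else seq_len(n)
  }
  out <- vapply(seq_len(n - 2L), function(i) median(x[i:(i + 2L)]),
                numeric(1))
  out_years <- switch(alignment,
                      trailing = years[3:n],
                      centered = years[2:(n - 1L)])
  setNames(out, out_years)
}

# 3-fold cross-validated correlation between out-of-fold predicted
# probability and the 0/1 labels.
.cv_correlation <- function(X, y, k = 3L, seed, ntree, max_depth) {
  n <- nrow(X)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    tr <- folds != f
    m <- bagged_trees(X[tr, , drop = FALSE], y[tr], ntree = ntree,
                      max_depth = max_depth, seed = seed + f)
    pred[!tr] <- predict(m, X[!tr, , drop = FALSE])
  }
  if (sd(pred) < 1e-12 || sd(y) < 1e-12) return(0)
  cor(pred, y)
}

#' Train the probabilistic forest/non-forest classifier
#'
#' Bagged-tree binary classifier on reflectance bands plus elevation;
#' the ensemble vote fraction is the forest-membership probability.
#' Returns a 3-fold cross-validated correlation between out-of-fold
#' probabilities and the labels as the quality score. For stable-class
#' training points, band values should be averaged across years before
#' calling (see [average_training_bands()]).
#'
#' @param training data.frame with predictor columns `band_1..band_7`
#'   and `elevation` (any all-numeric predictor set is accepted) and a
#'   `label` column coded 0/1 or "forest"/"non_forest".
#' @param seed integer seed.
#' @param ntree,max_depth ensemble controls.
#' @return object of class `"forest_classifier"` with elements `model`,
#'   `cv_r`, `predictors`, `n_train`.
#' @export
train_forest_classifier <- function(training, seed = 1L, ntree = 100L,
                                    max_depth = 8L) {
  stopifnot(is.data.frame(training), "label" %in% names(training))
  y <- training$label
  if (!is.numeric(y)) y <- as.integer(y %in% c("forest", "1", "TRUE"))
  if (nrow(training) < 30L)
    stop("need at least 30 training records", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  preds <- setdiff(names(training), "label")
  X <- as.matrix(training[preds])
  stopifnot(is.numeric(X))
  cv_r <- .cv_correlation(X, y, 3L, seed, ntree, max_depth)
  model <- bagged_trees(X, y, ntree = ntree, max_depth = max_depth,
                        seed = seed)
  structure(list(model = model, cv_r = cv_r, predictors = preds,
                 n_train = nrow(training)),
            class = "forest_classifier")
}

#' Average band values across years for stable training points
#'
#' @param refl year x band x row x col reflectance array.
#' @param rows,cols pixel indices of the training points.
#' @return matrix (points x band) of multi-year mean band values.
#' @export
average_training_bands <- function(refl, rows, cols) {
  stopifnot(length(rows) == length(cols))
  out <- matrix(NA_real_, length(rows), dim(refl)[2])
  colnames(out) <- paste0("band_", seq_len(dim(refl)[2]))
  for (i in seq_along(rows))
    out[i, ] <- colMeans(refl[, , rows[i], cols[i], drop = FALSE][, , 1, 1],
                         na.rm = TRUE)
  out
}

#' Predict annual forest-probability maps
#'
#' Applies a trained classifier to each year of a reflectance stack.
#' Pixels with all-missing predictors stay missing (NA), never 0.
#'
#' @param classifier a [train_forest_classifier()] result.
#' @param reflectance year x band x row x col array.
#' @param elevation row x col matrix.
#' @return year x row x col probability array in \[0, 1\].
#' @export
predict_probability <- function(classifier, reflectance, elevation) {
  stopifnot(inherits(classifier, "forest_classifier"),
            length(dim(reflectance)) == 4L)
  nb <- dim(reflectance)[2]
  if (nb + 1L != length(classifier$predictors))
    stop("band count mismatch: classifier expects ",
         length(classifier$predictors) - 1L, " bands + elevation, got ",
         nb, call. = FALSE)
  ny <- dim(reflectance)[1]; nr <- dim(reflectance)[3]; nc <- dim(reflectance)[4]
  out <- array(NA_real_, dim = c(ny, nr, nc))
  elev <- as.numeric(elevation)
  for (iy in seq_len(ny)) {
    X <- cbind(matrix(aperm(reflectance[iy, , , , drop = FALSE],
                            c(3, 4, 2, 1)), nr * nc, nb), elev)
    ok <- rowSums(is.na(X)) == 0L
    pr <- rep(NA_real_, nr * nc)
    if (any(ok)) pr[ok] <- clamp01(predict(classifier$model,
                                           X[ok, , drop = FALSE]))
    out[iy, , ] <- matrix(pr, nr, nc)
  }
  out
}
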