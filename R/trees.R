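## Compact CART regression trees with bagging and stochastic gradient
## boosting. These back the probabilistic forest/non-forest classifier
## (bagged trees, class labels coded 0/1 so the ensemble mean is a
## probability) and the carbon-density regressor (boosted trees).

# A tree is a data.frame of nodes: id, feature (0 = leaf), threshold,
# left/right child ids, value (node mean). Splits maximise SSE reduction.

.best_split <- function(x, y, min_node) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(ys)
  if (n < 2L * min_node) return(NULL)
  cs <- cumsum(ys)
  cs2 <- cumsum(ys^2)
  i <- seq_len(n - 1L)
  # candidate split after position i requires a strict value change
  ok <- (xs[i] < xs[i + 1L]) & (i >= min_node) & ((n - i) >= min_node)
  if (!any(ok)) return(NULL)
  nl <- i
  nr <- n - i
  sse_l <- cs2[i] - cs[i]^2 / nl
  sse_r <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / nr
  tot <- sse_l + sse_r
  tot[!ok] <- Inf
  j <- which.min(tot)
  if (!is.finite(tot[j])) return(NULL)
  list(threshold = (xs[j] + xs[j + 1L]) / 2, sse = tot[j])
}

.grow_tree <- function(X, y, idx, depth, max_depth, min_node, mtry, acc, rng_feats) {
  id <- acc$next_id
  acc$next_id <- id + 1L
  mu <- mean(y[idx])
  node_sse <- sum((y[idx] - mu)^2)
  make_leaf <- function() {
    acc$nodes[[id]] <- c(id = id, feature = 0L, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_, value = mu)
    id
  }
  if (depth >= max_depth || length(idx) < 2L * min_node || node_sse < 1e-12)
    return(make_leaf())
  p <- ncol(X)
  feats <- if (mtry < p) rng_feats(p, mtry) else seq_len(p)
  best <- NULL
  for (f in feats) {
    sp <- .best_split(X[idx, f], y[idx], min_node)
    if (!is.null(sp) && (is.null(best) || sp$sse < best$sse - 1e-12)) {
      best <- sp; best$feature <- f
    }
  }
  if (is.null(best) || best$sse >= node_sse - 1e-12) return(make_leaf())
  go_left <- X[idx, best$feature] <= best$threshold
  l <- .grow_tree(X, y, idx[go_left], depth + 1L, max_depth, min_node, mtry,
                  acc, rng_feats)
  r <- .grow_tree(X, y, idx[!go_left], depth + 1L, max_depth, min_node, mtry,
                  acc, rng_feats)
  acc$nodes[[id]] <- c(id = id, feature = best$feature,
                       threshold = best$threshold, left = l, right = r,
                       value = mu)
  id
}

#' Fit a single regression tree
#'
#' Axis-aligned CART regression tree grown by greedy SSE reduction.
#' Used as the base learner for [bagged_trees()] and [boosted_trees()].
#'
#' @param X numeric matrix of predictors (rows = cases).
#' @param y numeric response.
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_node minimum cases per child node.
#' @param mtry number of predictors sampled per split (default: all).
#' @return an object of class `"rtree"`.
#' @keywords internal
fit_rtree <- function(X, y, max_depth = 6L, min_node = 5L, mtry = ncol(X)) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1L)
  acc <- new.env(parent = emptyenv())
  acc$nodes <- list()
  acc$next_id <- 1L
  rng_feats <- function(p, m) sample.int(p, m)
  .grow_tree(X, y, seq_along(y), 0L, max_depth, min_node, mtry, acc, rng_feats)
  nodes <- do.call(rbind, acc$nodes)
  structure(list(nodes = nodes), class = "rtree")
}

#' @export
predict.rtree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  nodes <- object$nodes
  out <- numeric(nrow(X))
  recurse <- function(id, idx) {
    nd <- nodes[id, ]
    if (nd["feature"] == 0) {
      out[idx] <<- nd["value"]
      return(invisible(NULL))
    }
    go_left <- X[idx, nd["feature"]] <= nd["threshold"]
    if (any(go_left)) recurse(nd["left"], idx[go_left])
    if (any(!go_left)) recurse(nd["right"], idx[!go_left])
  }
  if (nrow(X) > 0L) recurse(1L, seq_len(nrow(X)))
  out
}

#' Bagged regression trees
#'
#' Bootstrap-aggregated CART trees. With a 0/1 response the ensemble
#' mean is a class-membership probability, which is how the
#' forest/non-forest classifier uses it.
#'
#' @inheritParams fit_rtree
#' @param ntree number of bootstrap trees.
#' @param seed integer seed (local RNG, does not disturb the caller's).
#' @return an object of class `"bagged_trees"`.
#' @export
bagged_trees <- function(X, y, ntree = 100L, max_depth = 8L, min_node = 2L,
                         mtry = max(1L, floor(sqrt(ncol(X)))), seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  trees <- with_seed(seed, lapply(seq_len(ntree), function(i) {
    b <- sample.int(nrow(X), nrow(X), replace = TRUE)
    fit_rtree(X[b, , drop = FALSE], y[b], max_depth, min_node, mtry)
  }))
  structure(list(trees = trees, p = ncol(X), colnames = colnames(X)),
            class = "bagged_trees")
}

#' @export
predict.bagged_trees <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$p) stop("predictor count mismatch: expected ",
                                object$p, ", got ", ncol(X))
  preds <- vapply(object$trees, predict, numeric(nrow(X)), newdata = X)
  if (nrow(X) == 1L) mean(preds) else rowMeans(preds)
}

#' Stochastic gradient-boosted regression trees
#'
#' Squared-loss gradient boosting with shallow CART base learners and
#' row subsampling; the regressor behind the carbon-density model.
#'
#' @inheritParams fit_rtree
#' @param n_rounds boosting iterations.
#' @param shrinkage learning rate.
#' @param subsample fraction of rows used per round.
#' @param seed integer seed.
#' @return an object of class `"boosted_trees"`.
#' @export
boosted_trees <- function(X, y, n_rounds = 300L, max_depth = 3L,
                          shrinkage = 0.1, subsample = 0.8, min_node = 5L,
                          seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  f0 <- mean(y)
  fit <- rep(f0, length(y))
  trees <- vector("list", n_rounds)
  with_seed(seed, {
    for (m in seq_len(n_rounds)) {
      res <- y - fit
      rows <- if (subsample < 1) {
        sort(sample.int(nrow(X), max(2L, floor(subsample * nrow(X)))))
      } else seq_len(nrow(X))
      tr <- fit_rtree(X[rows, , drop = FALSE], res[rows], max_depth, min_node)
      trees[[m]] <- tr
      fit <- fit + shrinkage * predict(tr, X)
    }
  })
  structure(list(f0 = f0, trees = trees, shrinkage = shrinkage, p = ncol(X),
                 colnames = colnames(X)),
            class = "boosted_trees")
}

#' @export
predict.boosted_trees <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$p) stop("predictor count mismatch: expected ",
                                object$p, ", got ", ncol(X))
  out <- rep(object$f0, nrow(X))
  for (tr in object$trees) out <- out + object$shrinkage * predict(tr, X)
  out
}
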