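# Gini impurity of a 0/1 label vector.
gini <- function(y) {
  p <- mean(y)
  2 * p * (1 - p)
}

# Best split of one node: returns list(feature, threshold, gain) or NULL.
# Ties resolve to the lowest feature index, then the lowest threshold, by
# scanning in that order and keeping only strictly better gains.
best_split <- function(X, y, min_leaf) {
  n <- length(y)
  g0 <- gini(y)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xs <- X[, j]
    ord <- order(xs)
    xo <- xs[ord]; yo <- y[ord]
    distinct <- which(diff(xo) > 0)
    if (length(distinct) == 0) next
    n_left <- distinct
    cum1 <- cumsum(yo)[distinct]
    p_l <- cum1 / n_left
    n_right <- n - n_left
    p_r <- (sum(yo) - cum1) / n_right
    w_gini <- (n_left * 2 * p_l * (1 - p_l) + n_right * 2 * p_r * (1 - p_r)) / n
    ok <- n_left >= min_leaf & n_right >= min_leaf
    if (!any(ok)) next
    for (i in which(ok)) {
      gain <- g0 - w_gini[i]
      thr <- (xo[distinct[i]] + xo[distinct[i] + 1]) / 2
      if (is.null(best) || gain > best$gain + 1e-12)
        best <- list(feature = j, threshold = thr, gain = gain)
    }
  }
  best
}

cart_grow <- function(X, y, depth, min_leaf, max_depth, min_decrease) {
  n <- length(y)
  node_class <- if (mean(y) > 0.5) 1L else 0L   # tie -> lower label
  leaf <- list(leaf = TRUE, class = node_class, prob = mean(y), n = n)
  if (length(unique(y)) == 1 || depth >= max_depth || n < 2 * min_leaf)
    return(leaf)
  sp <- best_split(X, y, min_leaf)
  if (is.null(sp) || sp$gain < min_decrease) return(leaf)
  go_left <- X[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       gain = sp$gain, n = n,
       left = cart_grow(X[go_left, , drop = FALSE], y[go_left],
                        depth + 1, min_leaf, max_depth, min_decrease),
       right = cart_grow(X[!go_left, , drop = FALSE], y[!go_left],
                         depth + 1, min_leaf, max_depth, min_decrease))
}

#' Fit a CART classification tree (Gini impurity)
#'
#' Greedy binary recursive partitioning: each node takes the axis-aligned
#' split `x_j <= t` (thresholds at midpoints of adjacent distinct values) that
#' most reduces weighted Gini impurity, with ties broken toward the lowest
#' feature index and then the lowest threshold. With `min_leaf = 1`, unlimited
#' depth and `min_decrease = 0` the tree memorizes any training set whose
#' identical rows share a label (zero-gain splits are permitted, which is what
#' lets the tree carve apart e.g. an XOR pattern). Deterministic given the
#' data.
#'
#' @param X numeric matrix of predictors.
#' @param y binary response (0/1, logical, or 2-level factor; second level = 1).
#' @param min_leaf minimum cases per leaf.
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_decrease minimum Gini decrease to accept a split.
#' @return object of class `"cart_tree"` (recursive node list).
#' @export
cart_fit <- function(X, y, min_leaf = 1, max_depth = Inf, min_decrease = 0) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (nrow(X) == 0) stop_bad("empty training data")
  if (!all(y %in% c(0L, 1L))) stop_bad("y must be binary")
  tree <- cart_grow(X, y, 0L, min_leaf, max_depth, min_decrease)
  structure(list(root = tree, p = ncol(X)), class = "cart_tree")
}

#' Predict classes from a CART tree
#'
#' @param tree a `"cart_tree"`.
#' @param X numeric matrix with the training column layout.
#' @return integer vector of 0/1 labels.
#' @export
cart_predict <- function(tree, X) {
  stopifnot(inherits(tree, "cart_tree"))
  X <- as.matrix(X)
  walk <- function(node, x) {
    while (!node$leaf)
      node <- if (x[node$feature] <= node$threshold) node$left else node$right
    node$class
  }
  vapply(seq_len(nrow(X)), function(i) walk(tree$root, X[i, ]), integer(1))
}

cart_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(cart_depth(node$left), cart_depth(node$right))
}
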