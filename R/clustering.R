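#' Standardize a feature matrix for clustering
#'
#' Centers each feature to mean 0 and scales to unit standard deviation. The
#' three features live on wildly different scales (pupil percent ~10, blink
#' rate ~0.05, normalized GSR ~0.005); without standardization K-means would
#' cluster on pupil dilation alone. Constant features are scaled by 1 with a
#' warning.
#'
#' @param X numeric matrix (rows = participants, cols = features).
#' @return list with `X` (scaled matrix), `center`, `scale`.
#' @export
standardize_features <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_bad("need at least two rows to standardize")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl == 0)) {
    warning("constant feature(s) scaled by 1: ",
            paste(colnames(X)[scl == 0], collapse = ", "), call. = FALSE)
    scl[scl == 0] <- 1
  }
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j + 1] <- sample.int(n, 1, prob = p)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j + 1], ])^2))
  }
  X[idx, , drop = FALSE]
}

#' K-means with k-means++ restarts
#'
#' Lloyd iterations (via [stats::kmeans()]) from k-means++ seedings; the best
#' of `n_init` restarts by within-cluster sum of squares is kept. Restarts that
#' produce an empty cluster are re-seeded. Deterministic given `seed`.
#'
#' @param X numeric matrix, typically standardized.
#' @param k number of clusters (`nrow(X) >= k`).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @param n_init number of restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @return a [stats::kmeans()] result object (fields `cluster`, `centers`,
#'   `tot.withinss`, `size`).
#' @export
kmeans_fit <- function(X, k, seed = NULL, n_init = 10, max_iter = 300) {
  X <- as.matrix(X)
  if (nrow(X) < k) stop_bad("need at least k = %d rows, got %d", k, nrow(X))
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  tries <- 0L
  while (tries < n_init * 3L) {
    tries <- tries + 1L
    km <- tryCatch(
      suppressWarnings(kmeans(X, centers = kmeanspp_centers(X, k),
                              iter.max = max_iter, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km) || any(km$size == 0)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    if (tries >= n_init && !is.null(best)) break
  }
  if (is.null(best)) stop_bad("k-means failed to produce %d nonempty clusters", k)
  best
}

#' Mean silhouette coefficient of a clustering
#'
#' For each point, `a` is its mean Euclidean distance to the other members of
#' its own cluster and `b` the smallest mean distance to any other cluster; the
#' silhouette is `(b - a) / max(a, b)`. Points in singleton clusters, and
#' points for which both means are zero, contribute 0. The cohort value is the
#' mean over points.
#'
#' @param X numeric matrix (use the same scaling as the clustering).
#' @param assignments integer cluster labels, every cluster nonempty, k >= 2.
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_mean <- function(X, assignments) {
  X <- as.matrix(X)
  cl <- as.integer(factor(assignments))
  k <- max(cl)
  if (k < 2) stop_bad("silhouette requires at least two clusters")
  n <- nrow(X)
  if (length(cl) != n) stop_bad("assignments length does not match rows")
  D <- as.matrix(dist(X))
  member <- vapply(seq_len(k), function(g) as.numeric(cl == g), numeric(n))
  sums <- D %*% member                       # n x k: total distance to each cluster
  sizes <- colSums(member)
  s <- numeric(n)
  for (i in seq_len(n)) {
    g <- cl[i]
    if (sizes[g] == 1) { s[i] <- 0; next }
    a <- sums[i, g] / (sizes[g] - 1)
    b <- min(sums[i, -g] / sizes[-g])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Silhouette score as a display percentage
#'
#' Affine map of the silhouette coefficient from `[-1, 1]` onto `[0, 100]`:
#' `50 * (s + 1)`, the transformation behind the published percentage column.
#'
#' @param s silhouette coefficient(s) in `[-1, 1]`.
#' @return percentage(s).
#' @export
silhouette_percentage <- function(s) {
  if (any(!is.finite(s)) || any(s < -1 - 1e-12) || any(s > 1 + 1e-12))
    stop_bad("silhouette values must lie in [-1, 1]")
  50 * (s + 1)
}

# Order clusters by decreasing pupil-dilation center (first feature column)
# for stable reporting; tags are assigned by the risk rules, not by index.
order_solution <- function(km, scaling, task_id, k) {
  centers_orig <- sweep(sweep(km$centers, 2, scaling$scale, "*"), 2,
                        scaling$center, "+")
  ord <- order(centers_orig[, 1], decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  structure(list(
    task_id = task_id, k = k,
    assignments = relabel[km$cluster],
    centers = centers_orig[ord, , drop = FALSE],
    centers_scaled = km$centers[ord, , drop = FALSE],
    sizes = km$size[ord],
    inertia = km$tot.withinss,
    silhouette = NA_real_, silhouette_pct = NA_real_,
    scaling = scaling), class = "cluster_solution")
}

#' Cluster one task's feature triples
#'
#' Standardizes (by default), runs [kmeans_fit()], computes the mean
#' silhouette on the clustered scale, and reports centers back in original
#' feature units with clusters ordered by decreasing pupil-dilation center.
#'
#' @param features data frame or matrix with columns `pupil_pct`, `blink_rate`,
#'   `gsr_norm` (one row per participant), or any numeric matrix.
#' @param k number of clusters.
#' @param seed optional seed for the restarts.
#' @param standardize cluster on z-scores (default) or raw units.
#' @param task_id identifier carried on the solution.
#' @param ... passed to [kmeans_fit()].
#' @return an object of class `"cluster_solution"`: `task_id`, `k`,
#'   `assignments` (1..k), `centers` (original units), `centers_scaled`,
#'   `sizes`, `inertia`, `silhouette`, `silhouette_pct`, `scaling`.
#' @export
cluster_task <- function(features, k, seed = NULL, standardize = TRUE,
                         task_id = NA_character_, ...) {
  X <- feature_matrix(features)
  sc <- if (standardize) standardize_features(X)
        else list(X = X, center = rep(0, ncol(X)),
                  scale = rep(1, ncol(X)))
  names(sc$center) <- names(sc$scale) <- colnames(X)
  km <- kmeans_fit(sc$X, k, seed = seed, ...)
  sol <- order_solution(km, sc, task_id, k)
  sol$silhouette <- silhouette_mean(sc$X, sol$assignments)
  sol$silhouette_pct <- silhouette_percentage(sol$silhouette)
  sol
}

feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    cols <- intersect(c("pupil_pct", "blink_rate", "gsr_norm"), names(features))
    if (length(cols) == 3) features <- features[, cols]
  }
  as.matrix(features)
}

#' Choose the cluster count by mean silhouette
#'
#' Fits every candidate k and returns the solution with the largest mean
#' silhouette; exact ties resolve to the smallest k. The silhouettes of all
#' candidates are attached for reporting.
#'
#' @inheritParams cluster_task
#' @param candidates cluster counts to try (default 2, 3, 4).
#' @return the winning `"cluster_solution"`, with a `candidates` data frame
#'   (k, silhouette, percentage) attached.
#' @export
select_k <- function(features, candidates = c(2, 3, 4), seed = NULL,
                     standardize = TRUE, task_id = NA_character_, ...) {
  if (length(candidates) == 0) stop_bad("no candidate cluster counts")
  candidates <- sort(unique(as.integer(candidates)))
  if (!is.null(seed)) set.seed(seed)
  sols <- lapply(candidates, function(k)
    cluster_task(features, k, seed = NULL, standardize = standardize,
                 task_id = task_id, ...))
  sil <- vapply(sols, `[[`, 0, "silhouette")
  best <- sols[[which.max(sil)]]     # ascending order => ties go to smallest k
  best$candidates <- data.frame(k = candidates, silhouette = sil,
                                percentage = silhouette_percentage(sil))
  best
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("K-means solution%s: k = %d, sizes = %s, silhouette = %.3f (%.1f%%)\n",
              if (is.na(x$task_id)) "" else paste0(" [", x$task_id, "]"),
              x$k, paste(x$sizes, collapse = "/"),
              x$silhouette, x$silhouette_pct))
  invisible(x)
}
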