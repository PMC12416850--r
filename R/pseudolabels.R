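#' One-hot indicator matrix from integer labels
#'
#' @param labels integer vector in `1..c` (length n).
#' @param c number of clusters (rows of the indicator).
#' @return binary c x n matrix whose column m has a single 1 at row
#'   `labels[m]`.
#' @export
indicator_from_labels <- function(labels, c) {
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > c))
    stop("labels must lie in 1..c (c = ", c, ")")
  n <- length(labels)
  Y <- matrix(0, c, n)
  Y[cbind(labels, seq_len(n))] <- 1
  Y
}

# k-means++ seeding on rows of `pts`, deterministic given the RNG state
kmeanspp_centers <- function(pts, c) {
  n <- nrow(pts)
  idx <- integer(c)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(pts, 2L, pts[idx[1L], ], `-`)^2)
  for (t in seq_len(c - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[t + 1L] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, rowSums(sweep(pts, 2L, pts[idx[t + 1L], ], `-`)^2))
  }
  pts[idx, , drop = FALSE]
}

# Lloyd's algorithm with k-means++ seeding, best of n_restarts by total
# within-cluster sum of squares; restarts that hit an empty cluster are
# reseeded. Deterministic given `seed`.
kmeans_restarts <- function(pts, c, seed, n_restarts = 10) {
  n <- nrow(pts)
  if (c > n) stop("cannot form c = ", c, " clusters from n = ", n, " points")
  if (c == n) {
    return(list(cluster = seq_len(n), centers = pts, tot.withinss = 0))
  }
  best <- NULL
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    fitr <- NULL
    for (attempt in 1:5) {   # reseed on empty-cluster failures
      ctr <- kmeanspp_centers(pts, c)
      fitr <- tryCatch(
        stats::kmeans(pts, centers = ctr, iter.max = 100,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fitr)) break
    }
    if (is.null(fitr)) next
    if (is.null(best) || fitr$tot.withinss < best$tot.withinss) best <- fitr
  }
  if (is.null(best)) stop("k-means failed in every restart")
  best
}

#' Per-omic pseudo-labels by k-means
#'
#' Clusters the cells of one omic (cells as points in feature space) into c
#' groups with Lloyd's algorithm, k-means++ seeding, best of `n_restarts` by
#' within-cluster sum of squares. The resulting one-hot matrix `Y` is used as
#' a soft prior during the joint factorization (`Y ~ Q V`), never as ground
#' truth; it is computed once and held fixed. The cluster-index permutation
#' is arbitrary — the projection `Q` absorbs it, so no alignment across omics
#' is attempted.
#'
#' @param omic an [omic_matrix] (normally preprocessed).
#' @param c number of clusters, `2 <= c <= n`.
#' @param seed RNG seed; the whole procedure is deterministic given it.
#' @param n_restarts k-means restarts (default 10).
#' @return list with `Y` (binary c x n indicator) and `labels` (integer
#'   vector in 1..c), class `pseudo_labels`.
#' @export
kmeans_pseudolabels <- function(omic, c, seed = 1, n_restarts = 10) {
  pts <- t(as.matrix(omic$values))
  km <- kmeans_restarts(pts, c, seed = seed, n_restarts = n_restarts)
  structure(list(Y = indicator_from_labels(km$cluster, c),
                 labels = as.integer(km$cluster), omic = omic$name),
            class = "pseudo_labels")
}
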