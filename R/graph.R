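#' Graph Laplacian from a binary adjacency
#'
#' Given a symmetric 0/1 adjacency with zero diagonal, forms the degree
#' matrix `D` (`D_ii` = number of edges at node i) and the combinatorial
#' Laplacian `L = D - A`. `L` is positive semidefinite with zero row sums;
#' the multiplicity of its zero eigenvalue equals the number of connected
#' components.
#'
#' @param A n x n binary symmetric adjacency (base or `Matrix`), zero
#'   diagonal.
#' @return object of class `cell_graph`: list with sparse `A`, `D`, `L`.
#' @export
graph_laplacian <- function(A) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (!Matrix::isSymmetric(A)) stop("adjacency must be symmetric")
  if (any(Matrix::diag(A) != 0)) stop("adjacency must have a zero diagonal")
  if (length(A@x) && !all(A@x %in% c(0, 1)))
    stop("adjacency must be binary (0/1)")
  deg <- Matrix::rowSums(A)
  D <- Matrix::Diagonal(x = deg)
  structure(list(A = A, D = D, L = D - A, degree = deg),
            class = "cell_graph")
}

#' Cell-cell k-nearest-neighbour graph over a multi-omics dataset
#'
#' For each omic, every cell is connected to its `knn` nearest neighbours in
#' that omic's (preprocessed) feature space; each per-omic graph is
#' symmetrized by union (`max(A, t(A))`); per-omic graphs are then combined
#' elementwise by union (default) or intersection. The result is binary with
#' no self-loops. Distance ties are broken deterministically by cell index.
#'
#' @param x a [multi_omics] dataset (or a single [omic_matrix]).
#' @param knn neighbours per cell, `1 <= knn < n`.
#' @param metric `"euclidean"` or `"cosine"` (cosine ranks neighbours by
#'   angle, implemented as Euclidean on unit-normalized cells).
#' @param combine `"union"` or `"intersection"` across omics.
#' @return a `cell_graph` (see [graph_laplacian()]).
#' @export
build_knn_graph <- function(x, knn = 10,
                            metric = c("euclidean", "cosine"),
                            combine = c("union", "intersection")) {
  metric <- match.arg(metric)
  combine <- match.arg(combine)
  if (inherits(x, "omic_matrix")) x <- multi_omics(list(x))
  stopifnot(inherits(x, "multi_omics"))
  n <- n_cells(x)
  if (knn >= n) stop("knn must be < n (", n, ")")
  Acomb <- NULL
  for (om in x$omics) {
    A <- knn_adjacency(as.matrix(om$values), knn, metric)
    Acomb <- if (is.null(Acomb)) A else
      if (combine == "union") pmax(Acomb, A) else pmin(Acomb, A)
  }
  graph_laplacian(Acomb)
}

# kNN adjacency for one omic; m is features x cells (dense)
knn_adjacency <- function(m, knn, metric) {
  pts <- t(m)                                   # cells as rows
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(pts^2))
    nrm[nrm == 0] <- 1
    pts <- pts / nrm
  }
  n <- nrow(pts)
  sq <- rowSums(pts^2)
  D2 <- outer(sq, rep(1, n)) + outer(rep(1, n), sq) - 2 * tcrossprod(pts)
  D2 <- pmax(D2, 0)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    d <- D2[j, ]
    d[j] <- Inf
    nb <- order(d, seq_len(n))[seq_len(knn)]    # ties -> lowest cell index
    A[j, nb] <- 1
  }
  pmax(A, t(A))                                 # union symmetrization
}

#' Manifold smoothness of a representation over a cell graph
#'
#' Evaluates `Tr(G L G^T)`, which equals
#' \eqn{\tfrac12 \sum_{ij} A_{ij} \|g_{\cdot i} - g_{\cdot j}\|^2}: small
#' values mean columns of `G` vary little across graph edges. Always >= 0
#' because `L` is positive semidefinite; exactly 0 when `G` is constant on
#' every connected component.
#'
#' @param G c x n matrix (columns indexed by cells).
#' @param graph a `cell_graph`.
#' @return non-negative scalar.
#' @export
graph_smoothness <- function(G, graph) {
  stopifnot(inherits(graph, "cell_graph"), ncol(G) == nrow(graph$L))
  sum(as.matrix(G %*% graph$L) * G)   # = Tr(G L G^T)
}
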