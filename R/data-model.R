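#' Construct a single-omic matrix
#'
#' An `omic_matrix` holds one measurement layer over a common set of cells:
#' a non-negative features-by-cells matrix (d x n, cells are always columns)
#' together with feature identifiers and a modality tag. RNA and ATAC layers
#' are typically sparse; ADT layers (tens of proteins) are dense. Both dense
#' base matrices and `Matrix` sparse matrices are accepted and preserved.
#'
#' @param values numeric matrix or `Matrix::sparseMatrix`, features x cells,
#'   all entries finite and >= 0.
#' @param name omic label, e.g. `"RNA"`, `"ADT"`, `"ATAC"`.
#' @param feature_ids character vector of length `nrow(values)`; defaults to
#'   rownames, or `f1..fd` when absent. Must be unique.
#' @param modality one of `"rna"`, `"adt"`, `"atac"`, `"generic"`; used to
#'   pick a default preprocessing recipe.
#' @return an object of class `omic_matrix`.
#' @export
omic_matrix <- function(values, name = "omic", feature_ids = NULL,
                        modality = c("generic", "rna", "adt", "atac")) {
  modality <- match.arg(modality)
  if (is.null(dim(values)) || length(dim(values)) != 2L)
    stop("`values` must be a matrix (features x cells)")
  if (nrow(values) < 1L)
    stop("omic '", name, "' must have at least one feature")
  if (is.null(feature_ids)) {
    feature_ids <- rownames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(values)))
  }
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != nrow(values))
    stop("feature_ids length (", length(feature_ids), ") != nrow(values) (",
         nrow(values), ")")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature_ids in omic '", name, "'")
  check_nonneg_finite(values, paste0("omic '", name, "'"))
  structure(
    list(name = name, values = values, feature_ids = feature_ids,
         modality = modality),
    class = "omic_matrix")
}

# shared validator: entries finite and >= 0, works for dense and Matrix
check_nonneg_finite <- function(values, what) {
  if (methods::is(values, "sparseMatrix")) {
    x <- values@x
  } else {
    x <- values
  }
  if (length(x) && any(!is.finite(x)))
    stop(what, " contains non-finite entries")
  if (length(x) && min(x) < 0)
    stop(what, " contains negative entries; inputs must be non-negative")
  invisible(TRUE)
}

#' Construct a multi-omics dataset
#'
#' Bundles v >= 1 aligned [omic_matrix] layers measured on the same n cells,
#' in the same column order. Column alignment is a hard invariant: every
#' downstream operation assumes cell m is the same cell in every omic.
#'
#' @param omics list of [omic_matrix] objects (or a single one).
#' @param cell_ids character vector of n cell barcodes shared by all omics;
#'   defaults to the first omic's colnames, or `cell1..celln`.
#' @param true_labels optional integer/factor vector of length n, used only
#'   for evaluation, never by the model.
#' @return an object of class `multi_omics`.
#' @export
multi_omics <- function(omics, cell_ids = NULL, true_labels = NULL) {
  if (inherits(omics, "omic_matrix")) omics <- list(omics)
  if (!length(omics)) stop("need at least one omic")
  if (!all(vapply(omics, inherits, logical(1), "omic_matrix")))
    stop("`omics` must be a list of omic_matrix objects")
  n <- ncol(omics[[1L]]$values)
  if (is.null(cell_ids)) {
    cell_ids <- colnames(omics[[1L]]$values)
    if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  }
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != n)
    stop("cell_ids length (", length(cell_ids), ") != number of cells (", n, ")")
  for (om in omics) {
    if (ncol(om$values) != n)
      stop("omic '", om$name, "' has ", ncol(om$values),
           " cells but the dataset has ", n, ": cells must be aligned")
    cn <- colnames(om$values)
    if (!is.null(cn) && !identical(as.character(cn), cell_ids))
      stop("omic '", om$name, "' cell barcodes differ from dataset cell_ids ",
           "(same cells must appear in the same order in every omic)")
  }
  if (!is.null(true_labels)) {
    if (length(true_labels) != n)
      stop("true_labels length != number of cells")
    true_labels <- if (is.factor(true_labels) || is.character(true_labels))
      as.integer(as.factor(true_labels)) else as.integer(true_labels)
  }
  structure(list(omics = omics, cell_ids = cell_ids, true_labels = true_labels),
            class = "multi_omics")
}

#' @export
print.multi_omics <- function(x, ...) {
  cat("multi_omics dataset: ", length(x$cell_ids), " cells, ",
      length(x$omics), " omic(s)\n", sep = "")
  for (om in x$omics)
    cat("  - ", om$name, " [", om$modality, "]: ", nrow(om$values),
        " features, ", if (methods::is(om$values, "sparseMatrix"))
          "sparse" else "dense", "\n", sep = "")
  if (!is.null(x$true_labels))
    cat("  true labels: ", length(unique(x$true_labels)), " classes\n", sep = "")
  invisible(x)
}

#' Number of cells in a dataset
#' @param x a `multi_omics` dataset.
#' @return integer n.
#' @export
n_cells <- function(x) length(x$cell_ids)

#' Hyperparameters for the joint factorization
#'
#' Collects all model weights and solver controls. Defaults follow the
#' empirically recommended search ranges: `beta` and `delta` (cluster
#' structure and pseudo-label weights) default to 1e-2 inside \[1e-4, 10\],
#' `eta` (imputation sparsity) to 3 inside \[0, 5\], `gamma` (omic-weight
#' distribution exponent) to 4, `epsilon_graph` (Laplacian weight) to 1e-2.
#' The closed-form simplex update for the omic weights requires `gamma > 1`.
#'
#' @param beta weight of the cluster-structure term \eqn{\|V-CG\|_F^2}.
#' @param delta weight of the pseudo-label term \eqn{\|Y^i-Q^iV\|_F^2}.
#' @param eta imputation L1 weight.
#' @param gamma omic-weight exponent, strictly > 1.
#' @param epsilon_graph weight of the manifold term \eqn{Tr(GLG^T)}.
#' @param k latent dimension; `NULL` defaults to the number of clusters.
#' @param c number of clusters (may also be given to [plnmfg()] directly).
#' @param knn neighbours for the cell graph.
#' @param dropout_threshold posterior cutoff for dropout candidates, in \[0,1\].
#' @param dropout_method `"mixture"` (default) or `"detection_rate"`.
#' @param impute logical; apply the imputation block (scalar or one flag per
#'   omic).
#' @param warmup cap on burn-in iterations of the latent-representation
#'   stage used to seed the cluster-structure blocks (see [init_state()]);
#'   0 disables the warm-up.
#' @param block_inner inner iterations per factor block (U, V, Q) within
#'   each outer iteration, with early exit once the block stops moving;
#'   each block subproblem is thereby solved to approximate stationarity,
#'   which is what makes the outer loop converge in few iterations.
#' @param cg_inner inner iterations equilibrating the cluster-structure
#'   pair (C, G) within each outer iteration (with early exit once G stops
#'   moving); 1 recovers plain single-step block descent.
#' @param max_iter outer-iteration cap.
#' @param tol relative objective-change convergence tolerance.
#' @param seed RNG seed controlling initialization, k-means restarts, etc.
#' @param floor positive stabilizer added to multiplicative-update
#'   denominators.
#' @param n_restarts k-means restarts for pseudo-labels and initialization.
#' @param graph_metric `"euclidean"` or `"cosine"` for the kNN graph.
#' @param graph_combine `"union"` or `"intersection"` across omic graphs.
#' @return a validated list of class `plnmfg_hyperparameters`.
#' @export
plnmfg_hyperparameters <- function(beta = 1e-2, delta = 1e-2, eta = 3,
                                   gamma = 4, epsilon_graph = 1e-2,
                                   k = NULL, c = NULL, knn = 10,
                                   dropout_threshold = 0.5,
                                   dropout_method = c("mixture", "detection_rate"),
                                   impute = TRUE, warmup = 200,
                                   block_inner = 30, cg_inner = 50,
                                   max_iter = 100, tol = 1e-5, seed = 1,
                                   floor = 1e-10, n_restarts = 10,
                                   graph_metric = c("euclidean", "cosine"),
                                   graph_combine = c("union", "intersection")) {
  hp <- list(beta = beta, delta = delta, eta = eta, gamma = gamma,
             epsilon_graph = epsilon_graph, k = k, c = c, knn = knn,
             dropout_threshold = dropout_threshold,
             dropout_method = match.arg(dropout_method),
             impute = impute, warmup = warmup, block_inner = block_inner,
             cg_inner = cg_inner,
             max_iter = max_iter, tol = tol, seed = seed, floor = floor,
             n_restarts = n_restarts,
             graph_metric = match.arg(graph_metric),
             graph_combine = match.arg(graph_combine))
  validate_hyperparameters(hp)
  structure(hp, class = "plnmfg_hyperparameters")
}

validate_hyperparameters <- function(hp) {
  stopifnot(hp$beta >= 0, hp$delta >= 0, hp$eta >= 0, hp$epsilon_graph >= 0)
  if (hp$gamma <= 1)
    stop("gamma must be > 1: the closed-form simplex update for the omic ",
         "weights is only defined for gamma > 1")
  if (!is.null(hp$k) && hp$k < 1) stop("latent dimension k must be >= 1")
  if (!is.null(hp$c) && hp$c < 2) stop("need at least c = 2 clusters")
  if (hp$knn < 1) stop("knn must be >= 1")
  if (hp$dropout_threshold < 0 || hp$dropout_threshold > 1)
    stop("dropout_threshold must lie in [0, 1]")
  if (hp$tol <= 0) stop("tol must be > 0")
  if (hp$floor <= 0) stop("floor must be > 0")
  if (hp$max_iter < 1) stop("max_iter must be >= 1")
  if (hp$warmup < 0) stop("warmup must be >= 0")
  if (hp$cg_inner < 1) stop("cg_inner must be >= 1")
  if (hp$block_inner < 1) stop("block_inner must be >= 1")
  invisible(hp)
}
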