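#' Per-omic preprocessing
#'
#' Normalizes each omic with a named recipe, keeping every output
#' non-negative (an NMF requirement) and preserving shape:
#' \describe{
#'   \item{rna_lognorm}{scale each cell column to the median library size,
#'     then `log1p`. The standard log-normalization for count data.}
#'   \item{adt_clr_clip}{centered log-ratio per cell on `log1p` counts; CLR
#'     can go negative, so negatives are clipped to 0 afterwards (logged via
#'     a message). The usual transform for antibody-derived tags.}
#'   \item{atac_tfidf}{term frequency (per-cell peak frequency) times inverse
#'     document frequency `log(1 + n / (1 + df))`; non-negative by
#'     construction. Standard for chromatin accessibility.}
#'   \item{none}{identity, for matrices the user preprocessed already.}
#' }
#' All-zero cell columns are kept (library-size factor 1) with a warning so
#' cell alignment across omics is never broken.
#'
#' After its recipe, each omic is by default rescaled so the mean of its
#' positive entries is 1. The recipes produce values on wildly different
#' scales (TF-IDF entries are orders of magnitude below log-normalized
#' counts), and in a jointly factorized model the per-omic costs — hence
#' the adaptive omic weights — would otherwise encode measurement units
#' rather than information content.
#'
#' @param x a [multi_omics] dataset.
#' @param recipes character vector, one recipe per omic, or a single recipe
#'   recycled; `NULL` picks by modality (rna -> rna_lognorm,
#'   adt -> adt_clr_clip, atac -> atac_tfidf, generic -> none).
#' @param rescale logical; equalize omic scales after the recipes
#'   (default `TRUE`; a no-op for all-zero omics).
#' @return a [multi_omics] dataset with transformed values.
#' @export
preprocess_omics <- function(x, recipes = NULL, rescale = TRUE) {
  stopifnot(inherits(x, "multi_omics"))
  v <- length(x$omics)
  if (is.null(recipes)) {
    recipes <- vapply(x$omics, function(om)
      switch(om$modality, rna = "rna_lognorm", adt = "adt_clr_clip",
             atac = "atac_tfidf", "none"), character(1))
  }
  if (length(recipes) == 1L) recipes <- rep(recipes, v)
  if (length(recipes) != v)
    stop("need one recipe per omic (", v, "), got ", length(recipes))
  known <- c("rna_lognorm", "adt_clr_clip", "atac_tfidf", "none")
  bad <- setdiff(recipes, known)
  if (length(bad))
    stop("unknown preprocessing recipe(s): ", paste(bad, collapse = ", "))
  oms <- mapply(function(om, rec) {
    vals <- switch(rec,
      none         = om$values,
      rna_lognorm  = recipe_lognorm(om$values, om$name),
      adt_clr_clip = recipe_clr_clip(om$values),
      atac_tfidf   = recipe_tfidf(om$values))
    if (rescale) {
      pos_mean <- if (methods::is(vals, "sparseMatrix")) {
        if (length(vals@x) && any(vals@x > 0)) mean(vals@x[vals@x > 0]) else 0
      } else if (any(vals > 0)) mean(vals[vals > 0]) else 0
      if (pos_mean > 0) vals <- vals / pos_mean
    }
    omic_matrix(vals, name = om$name, feature_ids = om$feature_ids,
                modality = om$modality)
  }, x$omics, recipes, SIMPLIFY = FALSE)
  multi_omics(oms, cell_ids = x$cell_ids, true_labels = x$true_labels)
}

recipe_lognorm <- function(m, name) {
  lib <- Matrix::colSums(m)
  if (any(lib == 0))
    warning("omic '", name, "': ", sum(lib == 0),
            " all-zero cell column(s) kept with library-size factor 1")
  med <- stats::median(lib[lib > 0])
  fac <- ifelse(lib > 0, med / lib, 1)
  if (methods::is(m, "sparseMatrix")) {
    out <- m %*% Matrix::Diagonal(x = fac)
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(m)
    out
  } else {
    log1p(sweep(m, 2L, fac, `*`))
  }
}

recipe_clr_clip <- function(m) {
  m <- as.matrix(m)                 # ADT panels are small; dense is fine
  lg <- log1p(m)
  out <- sweep(lg, 2L, colMeans(lg), `-`)
  nneg <- sum(out < 0)
  if (nneg) message("CLR produced ", nneg,
                    " negative entries; clipped to 0 for non-negativity")
  pmax(out, 0)
}

recipe_tfidf <- function(m) {
  lib <- Matrix::colSums(m)
  df <- Matrix::rowSums(m > 0)
  n <- ncol(m)
  idf <- log(1 + n / (1 + df))
  fac <- ifelse(lib > 0, 1 / lib, 1)
  if (methods::is(m, "sparseMatrix")) {
    out <- Matrix::Diagonal(x = idf) %*% m %*% Matrix::Diagonal(x = fac)
    dimnames(out) <- dimnames(m)
    methods::as(out, "CsparseMatrix")
  } else {
    sweep(m, 2L, fac, `*`) * idf
  }
}
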