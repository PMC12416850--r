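#' Read a multi-omics dataset from disk
#'
#' Three on-disk layouts are supported, one directory per dataset:
#' \describe{
#'   \item{mtx}{one subdirectory per omic holding `matrix.mtx` (features x
#'     cells), `features.tsv` and `barcodes.tsv` (the CellRanger dialect).}
#'   \item{csv}{one `<omic>.csv` per omic: features as rows, first column the
#'     feature id, header row of cell ids.}
#'   \item{h5}{a single `dataset.h5` with one group per omic (`values`,
#'     `feature_ids`, `modality`) and a shared top-level `cell_ids`.}
#' }
#' Cell barcodes must be identical, in identical order, across omics: the
#' reader raises an alignment error rather than silently reordering.
#'
#' @param dir dataset directory (for `h5`, the directory holding
#'   `dataset.h5`).
#' @param format one of `"mtx"`, `"csv"`, `"h5"`.
#' @param omics optional character vector restricting/ordering the omics to
#'   load; default: all found, alphabetically.
#' @return a [multi_omics] dataset.
#' @seealso [write_multi_omics()] for the inverse operation.
#' @export
read_multi_omics <- function(dir, format = c("mtx", "csv", "h5"), omics = NULL) {
  format <- match.arg(format)
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  truth <- NULL
  truth_path <- file.path(dir, "true_labels.csv")
  if (file.exists(truth_path)) {
    tl <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
    truth <- tl$label
  }
  switch(format,
    mtx = read_mtx_dataset(dir, omics, truth),
    csv = read_csv_dataset(dir, omics, truth),
    h5  = read_h5_dataset(dir, omics, truth))
}

read_mtx_dataset <- function(dir, omics, truth) {
  subs <- if (is.null(omics)) {
    sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  } else omics
  subs <- subs[file.exists(file.path(dir, subs, "matrix.mtx"))]
  if (!length(subs)) stop("no omic subdirectories with matrix.mtx under ", dir)
  cell_ids <- NULL
  oms <- lapply(subs, function(s) {
    p <- file.path(dir, s)
    m <- methods::as(Matrix::readMM(file.path(p, "matrix.mtx")), "CsparseMatrix")
    feats <- readLines(file.path(p, "features.tsv"))
    feats <- vapply(strsplit(feats, "\t"), `[[`, character(1), 1L)
    bcs <- readLines(file.path(p, "barcodes.tsv"))
    if (length(feats) != nrow(m) || length(bcs) != ncol(m))
      stop("sidecar TSVs do not match matrix dimensions in ", p)
    if (is.null(cell_ids)) cell_ids <<- bcs
    else if (length(bcs) != length(cell_ids))
      stop("omic '", s, "' has ", length(bcs), " cells; expected ",
           length(cell_ids), " — omics must share aligned cells")
    else if (!identical(bcs, cell_ids))
      stop("omic '", s, "' barcodes differ in content or order from the ",
           "first omic: refusing to reorder silently")
    mk <- read_modality_tag(p, s)
    dimnames(m) <- list(feats, bcs)
    omic_matrix(m, name = s, feature_ids = feats, modality = mk)
  })
  multi_omics(oms, cell_ids = cell_ids, true_labels = truth)
}

read_csv_dataset <- function(dir, omics, truth) {
  files <- if (is.null(omics)) {
    sort(setdiff(list.files(dir, pattern = "\\.csv$"), "true_labels.csv"))
  } else paste0(omics, ".csv")
  if (!length(files)) stop("no omic CSV files under ", dir)
  cell_ids <- NULL
  oms <- lapply(files, function(f) {
    nm <- sub("\\.csv$", "", f)
    df <- utils::read.csv(file.path(dir, f), check.names = FALSE,
                          stringsAsFactors = FALSE)
    feats <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    bcs <- colnames(m)
    if (is.null(cell_ids)) cell_ids <<- bcs
    else if (!identical(bcs, cell_ids))
      stop("omic '", nm, "' cell ids differ in count or order from the first ",
           "omic: refusing to reorder silently")
    rownames(m) <- feats
    mk <- read_modality_tag(dir, nm)
    omic_matrix(m, name = nm, feature_ids = feats, modality = mk)
  })
  multi_omics(oms, cell_ids = cell_ids, true_labels = truth)
}

# modality tags live in an optional sidecar "<omic>.modality" or
# "modality.txt"; default "generic"
read_modality_tag <- function(dir, name) {
  for (f in c(file.path(dir, paste0(name, ".modality")),
              file.path(dir, "modality.txt"))) {
    if (file.exists(f)) {
      tag <- trimws(readLines(f, n = 1L))
      if (tag %in% c("rna", "adt", "atac", "generic")) return(tag)
    }
  }
  "generic"
}

read_h5_dataset <- function(dir, omics, truth) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("h5 support requires the rhdf5 package")
  path <- file.path(dir, "dataset.h5")
  if (!file.exists(path)) stop("no dataset.h5 under ", dir)
  cell_ids <- as.character(rhdf5::h5read(path, "cell_ids"))
  groups <- rhdf5::h5ls(path)
  top <- groups$name[groups$group == "/" & groups$otype == "H5I_GROUP"]
  nms <- if (is.null(omics)) sort(top) else omics
  oms <- lapply(nms, function(nm) {
    vals <- rhdf5::h5read(path, paste0(nm, "/values"))
    feats <- as.character(rhdf5::h5read(path, paste0(nm, "/feature_ids")))
    mk <- as.character(rhdf5::h5read(path, paste0(nm, "/modality")))
    if (ncol(vals) != length(cell_ids))
      stop("omic '", nm, "' has ", ncol(vals), " cells; expected ",
           length(cell_ids))
    dimnames(vals) <- list(feats, cell_ids)
    omic_matrix(vals, name = nm, feature_ids = feats, modality = mk)
  })
  multi_omics(oms, cell_ids = cell_ids, true_labels = truth)
}

#' Write a multi-omics dataset to disk
#'
#' Inverse of [read_multi_omics()]: `read(write(x))` reproduces the values to
#' full precision (csv, h5) or sparse-exactly (mtx, which stores only
#' nonzeros). True labels, when present, are written to `true_labels.csv`.
#'
#' @param x a [multi_omics] dataset.
#' @param dir output directory (created if needed).
#' @param format one of `"mtx"`, `"csv"`, `"h5"`.
#' @return `dir`, invisibly.
#' @export
write_multi_omics <- function(x, dir, format = c("mtx", "csv", "h5")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "multi_omics"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  if (!is.null(x$true_labels))
    utils::write.csv(
      data.frame(cell_id = x$cell_ids, label = x$true_labels),
      file.path(dir, "true_labels.csv"), row.names = FALSE)
  switch(format,
    mtx = write_mtx_dataset(x, dir),
    csv = write_csv_dataset(x, dir),
    h5  = write_h5_dataset(x, dir))
  invisible(dir)
}

write_mtx_dataset <- function(x, dir) {
  for (om in x$omics) {
    p <- file.path(dir, om$name)
    dir.create(p, showWarnings = FALSE)
    m <- methods::as(methods::as(Matrix::Matrix(om$values, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(m, file.path(p, "matrix.mtx"))
    writeLines(om$feature_ids, file.path(p, "features.tsv"))
    writeLines(x$cell_ids, file.path(p, "barcodes.tsv"))
    writeLines(om$modality, file.path(p, paste0(om$name, ".modality")))
  }
}

write_csv_dataset <- function(x, dir) {
  for (om in x$omics) {
    m <- as.matrix(om$values)
    df <- data.frame(feature_id = om$feature_ids, m, check.names = FALSE)
    colnames(df) <- c("feature_id", x$cell_ids)
    utils::write.csv(df, file.path(dir, paste0(om$name, ".csv")),
                     row.names = FALSE)
    writeLines(om$modality, file.path(dir, paste0(om$name, ".modality")))
  }
}

write_h5_dataset <- function(x, dir) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("h5 support requires the rhdf5 package")
  path <- file.path(dir, "dataset.h5")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(x$cell_ids, path, "cell_ids")
  for (om in x$omics) {
    rhdf5::h5createGroup(path, om$name)
    rhdf5::h5write(as.matrix(om$values), path, paste0(om$name, "/values"))
    rhdf5::h5write(om$feature_ids, path, paste0(om$name, "/feature_ids"))
    rhdf5::h5write(om$modality, path, paste0(om$name, "/modality"))
  }
  rhdf5::h5closeAll()
}
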