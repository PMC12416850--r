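#' End-to-end run from a configuration
#'
#' Orchestrates the whole pipeline from a config (a named list or the path
#' of a YAML file): read the dataset, preprocess, fit, write artifacts. The
#' config mirrors the function arguments:
#' \preformatted{
#' input: path/to/dataset        # directory, see read_multi_omics()
#' format: mtx | csv | h5
#' output: path/to/outdir
#' c: 3
#' recipes: [rna_lognorm, adt_clr_clip]   # optional; default by modality
#' hyperparameters: {beta: 0.01, delta: 0.01, eta: 3, gamma: 4, seed: 1, ...}
#' no_pseudolabel: false         # ablation: delta <- 0 (the "NL" variant)
#' no_graph: false               # ablation: epsilon_graph <- 0 ("NG")
#' }
#' Artifacts written to `output`: `labels.csv` (cell_id, cluster), `V.csv`,
#' `G.csv`, `history.json` (objective breakdown, alpha trajectory,
#' convergence flag, variant name), `metrics.json` when true labels are
#' available, `pseudo_labels_<omic>.csv`, `config.json` (every default in
#' effect, for exact reruns) and `run.log`.
#'
#' @param config named list or path to a YAML file.
#' @return the [plnmfg_fit] object, invisibly; artifacts on disk.
#' @export
run_fit <- function(config) {
  cfg <- load_config(config)
  for (req in c("output", "c"))
    if (is.null(cfg[[req]])) stop("config error: missing field '", req, "'")
  x <- resolve_dataset(cfg)
  x <- preprocess_omics(x, cfg$recipes)
  hp <- do.call(plnmfg_hyperparameters, cfg$hyperparameters %||% list())
  variant <- "PLNMFG"
  if (isTRUE(cfg$no_pseudolabel)) { hp$delta <- 0; variant <- "PLNMFG_NL" }
  if (isTRUE(cfg$no_graph)) { hp$epsilon_graph <- 0
    variant <- if (variant == "PLNMFG") "PLNMFG_NG" else "PLNMFG_NL_NG" }
  out <- cfg$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run.log")
  logline <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logline("variant: ", variant)
  logline("hyperparameters: ",
          jsonlite::toJSON(unclass(hp), auto_unbox = TRUE, null = "null"))

  fit <- plnmfg(x, c = cfg$c, hp = hp)

  utils::write.csv(data.frame(cell_id = fit$cell_ids, cluster = fit$labels),
                   file.path(out, "labels.csv"), row.names = FALSE)
  utils::write.csv(fit$state$V, file.path(out, "V.csv"), row.names = FALSE)
  utils::write.csv(fit$state$G, file.path(out, "G.csv"), row.names = FALSE)
  for (pl in fit$pseudo_labels)
    utils::write.csv(data.frame(cell_id = fit$cell_ids,
                                pseudo_label = pl$labels),
                     file.path(out, paste0("pseudo_labels_", pl$omic, ".csv")),
                     row.names = FALSE)
  hist <- list(variant = variant,
               objective = fit$history$objective,
               terms = fit$history[, setdiff(colnames(fit$history),
                                             c("iteration", "objective"))],
               alpha_trace = fit$alpha_trace,
               iterations = fit$iterations,
               converged = fit$converged)
  jsonlite::write_json(hist, file.path(out, "history.json"),
                       auto_unbox = TRUE, digits = NA)
  masked_frac <- vapply(seq_along(fit$masks), function(i) {
    zeros <- sum(as.matrix(x$omics[[i]]$values) == 0)
    if (zeros == 0) 0 else sum(fit$masks[[i]]) / zeros
  }, numeric(1))
  logline("fraction of zeros masked per omic: ",
          paste(signif(masked_frac, 4), collapse = ", "))
  logline("iterations: ", fit$iterations, " converged: ", fit$converged)
  if (!is.null(x$true_labels)) {
    met <- clustering_metrics(fit$labels, x$true_labels)
    jsonlite::write_json(met, file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    logline("metrics: ", jsonlite::toJSON(met, auto_unbox = TRUE))
  }
  cfg$hyperparameters <- unclass(hp)
  jsonlite::write_json(cfg, file.path(out, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(fit)
}

#' Parameter sweep with metric evaluation
#'
#' Runs [plnmfg()] over the Cartesian grid of the supplied hyperparameter
#' values (any of `beta`, `delta`, `eta`, `gamma`, `epsilon_graph`, ...) and
#' scores each fit against the true labels. Rows are independent, so their
#' order carries no meaning.
#'
#' @param x a preprocessed [multi_omics] dataset with `true_labels`.
#' @param grid named list of hyperparameter value vectors.
#' @param c number of clusters.
#' @param hp base hyperparameters for everything not in the grid.
#' @param out optional path for a CSV copy of the table.
#' @return data.frame: one row per grid cell with the parameter values and
#'   `acc`, `ari`, `nmi`, `ami`; the best-ACC row index is attached as
#'   attribute `"best"`.
#' @export
run_sweep <- function(x, grid, c, hp = plnmfg_hyperparameters(), out = NULL) {
  if (!length(grid) || !all(lengths(grid) > 0))
    stop("config error: empty sweep grid")
  if (is.null(x$true_labels))
    stop("run_sweep needs true labels to score against")
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(r) {
    hpr <- hp
    for (nm in names(cells)) hpr[[nm]] <- cells[r, nm]
    fit <- plnmfg(x, c = c, hp = hpr)
    met <- clustering_metrics(fit$labels, x$true_labels)
    cbind(cells[r, , drop = FALSE], as.data.frame(met))
  })
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  attr(tab, "best") <- which.max(tab$acc)
  if (!is.null(out))
    utils::write.csv(tab, out, row.names = FALSE)
  tab
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config error: no such file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config error: expected a list or a YAML path")
  config
}

resolve_dataset <- function(cfg) {
  if (!is.null(cfg$dataset)) return(cfg$dataset)   # in-memory use
  if (is.null(cfg$input)) stop("config error: missing field 'input'")
  read_multi_omics(cfg$input, format = cfg$format %||% "mtx")
}
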