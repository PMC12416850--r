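#' Configuration for the multi-omics simulator
#'
#' Describes a cluster-structured paired multi-omics experiment: cells are
#' drawn from `c` clusters whose centroids live in a shared non-negative
#' latent space; every omic observes a non-negative linear mixture of the
#' same latent columns plus noise; dropout then zeroes entries with a
#' probability that decays logistically in the signal magnitude and is
#' modulated by per-cell sequencing depth (bright entries in deep cells are
#' rarely lost).
#'
#' @param n number of cells.
#' @param c number of clusters.
#' @param omics list of per-omic descriptions `list(name=, d=, modality=)`.
#' @param proportions cluster proportions (sum to 1); default equal.
#' @param k_true latent dimension of the generative factorization
#'   (default `c`).
#' @param separation minimum between-centroid distance in units of the
#'   within-cluster latent SD; 5-6 gives well-separated clusters that
#'   single-omic k-means mostly recovers, 1-2 gives heavy overlap.
#' @param noise `"gaussian_clipped"` (additive Gaussian, clipped at 0) or
#'   `"poisson"` (counts with the clean signal as rate).
#' @param noise_sd Gaussian noise SD relative to the mean clean signal.
#' @param dropout_rate target mean dropout probability over entries; the
#'   logistic intercept `a` is calibrated to hit it. Set 0 for no dropout.
#'   Ignored when `dropout_a` is given.
#' @param dropout_a logistic intercept, used directly when non-`NULL`
#'   (dropout probability `sigmoid(a - b * signal) * depth_factor`).
#' @param dropout_b logistic slope on the signal magnitude (>= 0).
#' @param dropout_depth overall depth-modulation strength in \[0, 1\]:
#'   per-cell factor `dropout_depth * (1 - 0.5 * rank_fraction(depth))`, so
#'   the deepest cell has half the dropout of the shallowest; 0 disables
#'   dropout entirely.
#' @param depth_sd SD of the per-cell log-normal depth multipliers.
#' @param seed RNG seed; simulation is deterministic given it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n, c, omics, proportions = NULL, k_true = c,
                       separation = 6,
                       noise = c("gaussian_clipped", "poisson"),
                       noise_sd = 0.1, dropout_rate = 0.3,
                       dropout_a = NULL, dropout_b = 1, dropout_depth = 1,
                       depth_sd = 0.3, seed = 1) {
  noise <- match.arg(noise)
  if (c > n) stop("infeasible: c > n")
  if (is.null(proportions)) proportions <- rep(1 / c, c)
  if (length(proportions) != c || abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must have length c and sum to 1")
  if (separation <= 0) stop("separation must be > 0")
  stopifnot(dropout_b >= 0, dropout_depth >= 0, dropout_depth <= 1,
            k_true >= 1)
  for (om in omics)
    if (is.null(om$d) || om$d < 1) stop("every omic needs a dimension d >= 1")
  structure(list(n = n, c = c, omics = omics, proportions = proportions,
                 k_true = k_true, separation = separation, noise = noise,
                 noise_sd = noise_sd, dropout_rate = dropout_rate,
                 dropout_a = dropout_a, dropout_b = dropout_b,
                 dropout_depth = dropout_depth, depth_sd = depth_sd,
                 seed = seed),
            class = "sim_config")
}

#' Simulator presets
#'
#' `sim1`: 530 cells, RNA 2,000 + ATAC 5,000 features, 3 types.
#' `sim2`: 1,000 cells, RNA 2,000 + ADT 30 features, 8 types.
#' `tiny`: 60 cells, 50 + 10 features, 3 types — a unit-test fixture.
#' Any [sim_config()] field can be overridden through `...` (e.g. `n = 200`
#' for a scaled-down sim1-shaped dataset).
#'
#' @param preset one of `"sim1"`, `"sim2"`, `"tiny"`.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_preset <- function(preset = c("sim1", "sim2", "tiny"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    sim1 = list(n = 530, c = 3,
                omics = list(list(name = "RNA", d = 2000, modality = "rna"),
                             list(name = "ATAC", d = 5000, modality = "atac"))),
    sim2 = list(n = 1000, c = 8,
                omics = list(list(name = "RNA", d = 2000, modality = "rna"),
                             list(name = "ADT", d = 30, modality = "adt"))),
    tiny = list(n = 60, c = 3,
                omics = list(list(name = "RNA", d = 50, modality = "rna"),
                             list(name = "ADT", d = 10, modality = "adt"))))
  args <- utils::modifyList(base, list(...))
  do.call(sim_config, args)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Simulate a cluster-structured multi-omics dataset with dropout
#'
#' Generative process (all seeded): each cluster centroid is a shared
#' uniform(0.5, 1) non-negative background plus a boost of
#' `separation / sqrt(2)` on its own latent axis — clusters are distinct
#' expression programs separated in direction (not just magnitude), with
#' between-centroid distances of about `separation` within-cluster SDs
#' (exactly so up to the background draw when `k_true >= c`; with
#' `k_true < c` clusters must share axes and the guarantee lapses); latent
#' columns
#' `V_true` are centroid + unit Gaussian noise clipped at 0; each omic's
#' loading `U_i` is uniform(0, 1); the clean signal `U_i V_true` is scaled
#' per cell by log-normal depth multipliers, observed through the noise
#' model, and finally entries are zeroed with probability
#' `sigmoid(a - b * signal) * depth_factor` — small signals in shallow cells
#' drop out most. Which zeros are dropout events (i.e. were nonzero before)
#' is recorded per omic.
#'
#' @param config a [sim_config()] or [sim_preset()].
#' @return list with `dataset` (a [multi_omics] with `true_labels` set) and
#'   `truth`: `labels`, `V`, `U` (list), `dropout_masks` (list of binary
#'   d x n matrices, subsets of the observed zeros), `depth`, `dropout_a`.
#' @export
simulate_multiomics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n; c <- config$c; k <- config$k_true
  labels <- sample(rep(seq_len(c),
                       times = proportion_counts(config$proportions, n)))
  # centroids: shared non-negative background plus one dominant latent axis
  # per cluster (distinct "programs"), so clusters differ in direction, not
  # just magnitude; the axis amplitude is set so the minimum between-centroid
  # distance equals `separation` (within-cluster latent SD is 1 per
  # coordinate)
  M <- matrix(stats::runif(k * c, 0.5, 1), k, c)
  if (c > 1) {
    amp <- config$separation / sqrt(2)
    axes <- rep(seq_len(k), length.out = c)
    M[cbind(axes, seq_len(c))] <- M[cbind(axes, seq_len(c))] + amp
  }
  V <- pmax(M[, labels, drop = FALSE] +
              matrix(stats::rnorm(k * n), k, n), 0)
  depth <- stats::rlnorm(n, 0, config$depth_sd)
  depth <- depth / mean(depth)
  rf <- if (n > 1) (rank(depth, ties.method = "first") - 1) / (n - 1) else 0
  depth_factor <- config$dropout_depth * (1 - 0.5 * rf)

  oms <- vector("list", length(config$omics))
  Ulist <- vector("list", length(config$omics))
  masks <- vector("list", length(config$omics))
  a_used <- NA_real_
  for (i in seq_along(config$omics)) {
    oc <- config$omics[[i]]
    U <- matrix(stats::runif(oc$d * k), oc$d, k)
    signal <- sweep(U %*% V, 2L, depth, `*`)
    obs <- switch(config$noise,
      gaussian_clipped = pmax(signal +
        matrix(stats::rnorm(length(signal), 0,
                            config$noise_sd * mean(signal)),
               nrow(signal), ncol(signal)), 0),
      poisson = matrix(stats::rpois(length(signal), signal),
                       nrow(signal), ncol(signal)))
    mask <- matrix(0, oc$d, n)
    a <- config$dropout_a
    if (is.null(a)) {
      a <- if (config$dropout_rate > 0 && config$dropout_depth > 0)
        calibrate_dropout_intercept(signal, config$dropout_b, depth_factor,
                                    config$dropout_rate) else -Inf
    }
    a_used <- a
    if (is.finite(a) && config$dropout_depth > 0) {
      p <- sweep(sigmoid(a - config$dropout_b * signal), 2L,
                 depth_factor, `*`)
      drop <- matrix(stats::runif(length(p)), nrow(p), ncol(p)) < p
      mask[drop & obs > 0] <- 1
      obs[drop] <- 0
    }
    feats <- paste0(oc$name, "_f", seq_len(oc$d))
    dimnames(obs) <- list(feats, paste0("cell", seq_len(n)))
    vals <- if (!is.null(oc$modality) && oc$modality %in% c("rna", "atac"))
      methods::as(Matrix::Matrix(obs, sparse = TRUE), "CsparseMatrix") else obs
    oms[[i]] <- omic_matrix(vals, name = oc$name, feature_ids = feats,
                            modality = oc$modality %||% "generic")
    Ulist[[i]] <- U
    masks[[i]] <- mask
  }
  dataset <- multi_omics(oms, cell_ids = paste0("cell", seq_len(n)),
                         true_labels = labels)
  list(dataset = dataset,
       truth = list(labels = labels, V = V, U = Ulist,
                    dropout_masks = masks, depth = depth,
                    dropout_a = a_used))
}

# integer cluster sizes from proportions, summing exactly to n
proportion_counts <- function(p, n) {
  cnt <- floor(p * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    frac <- p * n - cnt
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  cnt
}

# solve mean(sigmoid(a - b*s) * f) = rate for the intercept a
calibrate_dropout_intercept <- function(signal, b, depth_factor, rate) {
  mean_p <- function(a)
    mean(sweep(sigmoid(a - b * signal), 2L, depth_factor, `*`)) - rate
  upper_cap <- mean(depth_factor)
  if (rate >= upper_cap)
    stop("target dropout rate ", rate, " unreachable: depth modulation caps ",
         "the mean dropout probability at ", signif(upper_cap, 3))
  stats::uniroot(mean_p, lower = -100, upper = 100 + b * max(signal),
                 tol = 1e-8)$root
}

`%||%` <- function(a, b) if (is.null(a)) b else a
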