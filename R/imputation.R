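#' Per-cell sequencing-depth weights
#'
#' Deeply sequenced cells are expected to have lower dropout rates, so their
#' zero entries should be imputed less. The weight of cell j is its library
#' size relative to the mean: `u_j = libsize_j / mean(libsize)`, so
#' `mean(u) = 1` and deeper cells carry larger L1 penalties in the imputation
#' block. Scale-invariant in the counts.
#'
#' @param omic an [omic_matrix].
#' @return positive numeric vector of length n with mean 1.
#' @export
depth_weights <- function(omic) {
  lib <- as.numeric(Matrix::colSums(omic$values))
  if (all(lib == 0)) stop("omic '", omic$name, "' is all-zero: depth ",
                          "weights are undefined")
  if (any(lib == 0)) {
    warning("omic '", omic$name, "': ", sum(lib == 0), " zero library ",
            "size(s) replaced by the smallest positive library size")
    lib[lib == 0] <- min(lib[lib > 0])
  }
  lib / mean(lib)
}

#' Flag zero entries that look like dropout events
#'
#' Zeros in single-cell data mix true zeros (gene not expressed) with false
#' zeros (expression lost to sequencing). Only flagged entries may receive
#' imputed mass. A zero at (g, j) is flagged when its estimated dropout
#' probability strictly exceeds `threshold`.
#'
#' Two estimators are provided:
#' \describe{
#'   \item{mixture}{(default) a two-component model per feature with >= 10
#'     nonzero observations: the gene is expressed with prior
#'     `pi_g = min(1, detect_rate(g) / (1 - mean_zero_fraction))` and, if
#'     expressed, reads zero with a technical-failure probability estimated
#'     by the cell's own zero fraction `z_j` (deep cells have smaller `z_j`,
#'     so their zeros score lower). The score is the posterior of the
#'     expressed component: `pi_g * z_j / (pi_g * z_j + 1 - pi_g)`.
#'     Features with < 10 nonzero observations fall back to the
#'     detection-rate score.}
#'   \item{detection_rate}{a deterministic fallback:
#'     `detect_rate(g) * (1 - rank_fraction(libsize_j))`, where the
#'     shallowest cell has rank fraction 0.}
#' }
#'
#' @param omic an [omic_matrix].
#' @param threshold probability cutoff in \[0, 1\]; strict inequality, so
#'   `threshold = 1` masks nothing.
#' @param method `"mixture"` or `"detection_rate"`.
#' @return binary matrix (d x n, base dense) with 1 at dropout candidates;
#'   always a subset of the zero entries.
#' @export
detect_dropout_candidates <- function(omic, threshold = 0.5,
                                      method = c("mixture", "detection_rate")) {
  method <- match.arg(method)
  stopifnot(threshold >= 0, threshold <= 1)
  m <- as.matrix(omic$values)
  d <- nrow(m); n <- ncol(m)
  zero <- m == 0
  if (all(zero)) {
    warning("omic '", omic$name, "' is all-zero: no dropout candidates")
    return(matrix(0, d, n, dimnames = dimnames(m)))
  }
  if (!any(zero)) return(matrix(0, d, n, dimnames = dimnames(m)))
  lib <- colSums(m)
  detect <- rowMeans(!zero)
  # rank fraction of library size: shallowest cell -> 0, deepest -> 1
  rf <- if (n > 1) (rank(lib, ties.method = "average") - 1) / (n - 1) else 0
  score_dr <- outer(detect, 1 - rf)            # detection_rate score
  score <- if (method == "detection_rate") {
    score_dr
  } else {
    zfrac <- colMeans(zero)                    # per-cell technical-zero proxy
    pi_g <- pmin(1, detect / max(1 - mean(zfrac), 1e-12))
    post <- outer(pi_g, zfrac) /
      (outer(pi_g, zfrac) + outer(1 - pi_g, rep(1, n)))
    nz_count <- rowSums(!zero)
    low <- nz_count < 10                       # too few observations to fit
    if (any(low)) post[low, ] <- score_dr[low, , drop = FALSE]
    post
  }
  mask <- (zero & (score > threshold)) * 1
  dimnames(mask) <- dimnames(m)
  mask
}

#' Closed-form imputation block
#'
#' Exact minimizer of the imputation subproblem
#' \deqn{\min_{S \ge 0,\; supp(S) \subseteq mask}
#'   \|X + S - UV\|_F^2 + \eta \sum_j u_j \|S_{\cdot j}\|_1,}
#' which decouples entrywise into soft-thresholding: on masked positions
#' `S_gj = max(0, (UV - X)_gj - eta * u_j / 2)`, and 0 elsewhere.
#'
#' @param residual the matrix `UV - X` (d x n).
#' @param mask binary dropout-candidate matrix from
#'   [detect_dropout_candidates()].
#' @param u depth weights from [depth_weights()].
#' @param eta non-negative L1 weight.
#' @return non-negative d x n matrix supported on the mask.
#' @export
solve_imputation <- function(residual, mask, u, eta) {
  stopifnot(eta >= 0, all(dim(residual) == dim(mask)),
            length(u) == ncol(residual))
  S <- sweep(as.matrix(residual), 2L, eta * u / 2, `-`)
  S[mask == 0] <- 0
  pmax(S, 0)
}
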