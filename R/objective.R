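#' Joint objective of the factorization
#'
#' Direct summation of the full model objective
#' \deqn{F = \sum_i \alpha_i^\gamma \big\{ \|X^i + S^i - U^i V\|_F^2
#'   + \eta \sum_j u^i_j \|S^i_{\cdot j}\|_1
#'   + \delta \|Y^i - Q^i V\|_F^2 \big\}
#'   + \beta \|V - C G\|_F^2 + \varepsilon\, Tr(G L G^T).}
#' This function is the oracle every block update is tested against: it
#' evaluates each term by brute-force summation, with no shortcuts shared
#' with the update rules.
#'
#' @param state a `plnmfg_state` (see [init_state()]): lists `U`, `S`, `Q`
#'   and matrices `V`, `C`, `G`, weights `alpha`.
#' @param x a [multi_omics] dataset (values must match the state's shapes).
#' @param Y list of pseudo-label indicator matrices (c x n), one per omic.
#' @param graph a `cell_graph` over the same cells.
#' @param u list of depth-weight vectors, one per omic.
#' @param hp [plnmfg_hyperparameters()].
#' @return scalar objective with attribute `"terms"`: a named vector with
#'   the reconstruction, imputation-L1, pseudo-label, cluster-structure and
#'   smoothness components (already weighted).
#' @export
plnmfg_objective <- function(state, x, Y, graph, u, hp) {
  v <- length(x$omics)
  rec <- imp <- lab <- 0
  for (i in seq_len(v)) {
    w <- state$alpha[i]^hp$gamma
    Xi <- as.matrix(x$omics[[i]]$values)
    Ri <- Xi + state$S[[i]] - state$U[[i]] %*% state$V
    rec <- rec + w * sum(Ri^2)
    imp <- imp + w * hp$eta * sum(u[[i]] * colSums(abs(state$S[[i]])))
    if (hp$delta > 0)
      lab <- lab + w * hp$delta * sum((Y[[i]] - state$Q[[i]] %*% state$V)^2)
  }
  cs <- if (hp$beta > 0)
    hp$beta * sum((state$V - state$C %*% state$G)^2) else 0
  sm <- if (hp$epsilon_graph > 0)
    hp$epsilon_graph * graph_smoothness(state$G, graph) else 0
  terms <- c(reconstruction = rec, imputation_l1 = imp, pseudo_label = lab,
             cluster_structure = cs, smoothness = sm)
  if (any(!is.finite(terms)))
    stop("non-finite objective term(s): ",
         paste(names(terms)[!is.finite(terms)], collapse = ", "))
  structure(sum(terms), terms = terms)
}
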