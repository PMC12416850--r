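# Block updates for the alternating minimization. Each rule is a
# multiplicative (Lee-Seung style) or closed-form block minimizer of the
# joint objective; each one is guaranteed not to increase the objective, a
# property enforced at run time by fit() and tested against the
# direct-summation oracle in plnmfg_objective().

#' Multiplicative update of the per-omic basis matrices U
#'
#' `U_i <- U_i * ((X_i + S_i) V^T) / (U_i V V^T + floor)`. Fixed point at an
#' exact factorization; zero rows are absorbing (standard for multiplicative
#' rules).
#'
#' @param state a `plnmfg_state`.
#' @param x the dataset.
#' @param floor positive denominator stabilizer.
#' @return the state with updated `U`.
#' @export
update_U <- function(state, x, floor = 1e-10) {
  VT <- t(state$V)
  VVt <- state$V %*% VT
  for (i in seq_along(state$U)) {
    Xi <- as.matrix(x$omics[[i]]$values)
    num <- (Xi + state$S[[i]]) %*% VT
    den <- state$U[[i]] %*% VVt + floor
    state$U[[i]] <- state$U[[i]] * num / den
  }
  state
}

#' Multiplicative update of the unified representation V
#'
#' V couples every term but the smoothness penalty:
#' numerator `sum_i a_i^g (U_i^T (X_i + S_i) + delta Q_i^T Y_i) + beta C G`,
#' denominator `sum_i a_i^g (U_i^T U_i + delta Q_i^T Q_i) V + beta V`.
#' With `beta = delta = 0` and one omic this is the classical NMF
#' coefficient update.
#'
#' @inheritParams update_U
#' @param Y pseudo-label indicator list.
#' @param hp hyperparameters.
#' @return the state with updated `V`.
#' @export
update_V <- function(state, x, Y, hp) {
  k <- nrow(state$V); n <- ncol(state$V)
  num <- matrix(0, k, n)
  den <- matrix(0, k, n)
  for (i in seq_along(state$U)) {
    w <- state$alpha[i]^hp$gamma
    Ui <- state$U[[i]]
    Xi <- as.matrix(x$omics[[i]]$values)
    num <- num + w * crossprod(Ui, Xi + state$S[[i]])
    den <- den + w * (crossprod(Ui) %*% state$V)
    if (hp$delta > 0) {
      Qi <- state$Q[[i]]
      num <- num + w * hp$delta * crossprod(Qi, Y[[i]])
      den <- den + w * hp$delta * (crossprod(Qi) %*% state$V)
    }
  }
  if (hp$beta > 0) {
    num <- num + hp$beta * (state$C %*% state$G)
    den <- den + hp$beta * state$V
  }
  state$V <- state$V * num / (den + hp$floor)
  state
}

#' Multiplicative update of the pseudo-label projections Q
#'
#' `Q_i <- Q_i * (Y_i V^T) / (Q_i V V^T + floor)`, minimizing
#' `delta ||Y_i - Q_i V||_F^2` blockwise. Skipped (state unchanged) when
#' `delta = 0`.
#'
#' @inheritParams update_V
#' @return the state with updated `Q`.
#' @export
update_Q <- function(state, Y, hp) {
  if (hp$delta == 0) return(state)
  VT <- t(state$V)
  VVt <- state$V %*% VT
  for (i in seq_along(state$Q)) {
    num <- Y[[i]] %*% VT
    den <- state$Q[[i]] %*% VVt + hp$floor
    state$Q[[i]] <- state$Q[[i]] * num / den
  }
  state
}

#' Multiplicative update of the centroid matrix C
#'
#' `C <- C * (V G^T) / (C G G^T + floor)`, minimizing
#' `beta ||V - C G||_F^2` blockwise. Skipped when `beta = 0`.
#'
#' @inheritParams update_V
#' @return the state with updated `C`.
#' @export
update_C <- function(state, hp) {
  if (hp$beta == 0) return(state)
  GT <- t(state$G)
  num <- state$V %*% GT
  den <- state$C %*% (state$G %*% GT) + hp$floor
  state$C <- state$C * num / den
  state
}

#' Multiplicative update of the cluster indicator G
#'
#' Graph-regularized rule
#' `G <- G * (beta C^T V + eps G A) / (beta C^T C G + eps G D + floor)`,
#' minimizing `beta ||V - C G||_F^2 + eps Tr(G L G^T)` blockwise using the
#' Laplacian split `L = D - A` (both parts non-negative). With `eps = 0` or
#' an empty graph this is the plain coefficient update for `V ~ C G`.
#' Skipped when both `beta` and `eps` are 0.
#'
#' @inheritParams update_V
#' @param graph a `cell_graph`.
#' @return the state with updated `G`.
#' @export
update_G <- function(state, graph, hp) {
  b <- hp$beta; e <- hp$epsilon_graph
  if (b == 0 && e == 0) return(state)
  G <- state$G
  num <- matrix(0, nrow(G), ncol(G))
  den <- matrix(0, nrow(G), ncol(G))
  if (b > 0) {
    num <- num + b * crossprod(state$C, state$V)
    den <- den + b * (crossprod(state$C) %*% G)
  }
  if (e > 0) {
    num <- num + e * as.matrix(G %*% graph$A)
    den <- den + e * as.matrix(G %*% graph$D)
  }
  state$G <- G * num / (den + hp$floor)
  state
}

#' Closed-form omic weights on the simplex
#'
#' Minimizes `sum_i alpha_i^gamma f_i` subject to `sum alpha_i = 1`,
#' `alpha_i > 0` (Lagrangian solution):
#' `alpha_i = (1 / f_i)^{1 / (gamma - 1)} / sum_t (1 / f_t)^{1 / (gamma - 1)}`,
#' where `f_i` is omic i's bracketed cost (reconstruction + imputation L1 +
#' pseudo-label terms). Cheaper omics receive larger weights; `gamma` near 1
#' concentrates all weight on the cheapest omic, large `gamma` flattens the
#' distribution. If some costs are exactly zero, the weight is split
#' uniformly among the zero-cost omics (the limit case).
#'
#' @param f positive per-omic cost vector (length v).
#' @param gamma exponent > 1.
#' @return weight vector on the open simplex.
#' @export
update_alpha <- function(f, gamma) {
  stopifnot(gamma > 1, all(f >= 0))
  if (any(f == 0)) {
    a <- as.numeric(f == 0)
    return(a / sum(a))
  }
  w <- (1 / f)^(1 / (gamma - 1))
  w / sum(w)
}

# per-omic bracketed costs f_i used by update_alpha (no alpha weighting)
omic_costs <- function(state, x, Y, u, hp) {
  vapply(seq_along(x$omics), function(i) {
    Xi <- as.matrix(x$omics[[i]]$values)
    f <- sum((Xi + state$S[[i]] - state$U[[i]] %*% state$V)^2) +
      hp$eta * sum(u[[i]] * colSums(abs(state$S[[i]])))
    if (hp$delta > 0)
      f <- f + hp$delta * sum((Y[[i]] - state$Q[[i]] %*% state$V)^2)
    f
  }, numeric(1))
}
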