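#' Initialize the factorization state
#'
#' Seeded initialization: omic weights uniform (1/v); `U_i` and `V` drawn
#' uniform(0, 1) and rescaled so that `mean(U_i V)` matches each omic's mean
#' value; `Q_i` drawn uniform then refined by one multiplicative step toward
#' `Y_i ~ Q_i V` (so the pseudo-label term starts in a sensible range);
#' `S_i = 0`. The random blocks are then warmed up by burn-in iterations of
#' the latent-representation stage alone (S, U, V, Q and the omic weights —
#' everything except the cluster-structure and graph blocks), run until
#' that stage's objective stabilizes to the fit tolerance or `warmup`
#' iterations are reached. Finally `C` and `G` are seeded by k-means on the
#' columns of the warmed `V` (`C` = centroids, `G` = one-hot assignments
#' shrunk toward uniform by 0.2 so no entry starts at the absorbing zero of
#' the multiplicative rule). Without the warm-up, k-means on a still-random
#' `V` would pin the indicator blocks to an arbitrary partition that a weak
#' `beta` coupling cannot escape; with it, the outer loop only has to fuse
#' the already-converged representation with cluster-structure learning,
#' which takes few iterations.
#'
#' @param x a [multi_omics] dataset.
#' @param Y pseudo-label list (one c x n indicator per omic).
#' @param hp hyperparameters with `k` and `c` resolved.
#' @param masks optional dropout-candidate masks (list per omic) so the
#'   imputation block joins the burn-in; `NULL` keeps `S = 0`.
#' @param u depth-weight list per omic; defaults to all-ones.
#' @param warmup cap on burn-in iterations.
#' @return a list of class `plnmfg_state`.
#' @export
init_state <- function(x, Y, hp, masks = NULL, u = NULL, warmup = 200) {
  set.seed(hp$seed)
  v <- length(x$omics)
  n <- n_cells(x)
  k <- hp$k; c <- hp$c
  means <- vapply(x$omics, function(om) mean(om$values), numeric(1))
  vscale <- sqrt(4 * max(mean(means), 1e-8) / k)
  V <- matrix(stats::runif(k * n), k, n) * vscale
  U <- lapply(seq_len(v), function(i) {
    d <- nrow(x$omics[[i]]$values)
    uscale <- 4 * max(means[i], 1e-8) / (k * vscale)
    matrix(stats::runif(d * k), d, k) * uscale
  })
  S <- lapply(x$omics, function(om)
    matrix(0, nrow(om$values), n))
  Q <- lapply(seq_len(v), function(i) {
    Qi <- matrix(stats::runif(c * k), c, k)
    Qi * (Y[[i]] %*% t(V)) / (Qi %*% V %*% t(V) + hp$floor)
  })
  state <- structure(list(U = U, V = V, Q = Q, S = S, C = NULL, G = NULL,
                          alpha = rep(1 / v, v)),
                     class = "plnmfg_state")
  # burn-in on the latent-representation stage, run to its own (relative)
  # convergence so C/G are seeded from a V that already reflects the data
  hp0 <- hp; hp0$beta <- 0; hp0$epsilon_graph <- 0
  if (is.null(u)) u <- lapply(seq_len(v), function(i) rep(1, n))
  prev <- Inf
  wtol <- hp$tol / 10       # tighter than the outer loop, so the outer
                            # loop starts essentially stationary
  midx <- mask_index(masks)
  for (t in seq_len(warmup)) {
    state <- impute_step(state, x, midx, u, hp$eta)
    state <- update_U(state, x, hp$floor)
    state <- update_V(state, x, Y, hp0)
    state <- update_Q(state, Y, hp0)
    fcost <- pmax(omic_costs(state, x, Y, u, hp), hp$floor)
    if (v > 1) state$alpha <- update_alpha(fcost, hp$gamma)
    # with beta = epsilon = 0 the stage objective is exactly the weighted
    # cost sum, so no separate objective evaluation is needed
    f <- sum(state$alpha^hp$gamma * fcost)
    if (is.finite(prev) && abs(prev - f) / max(abs(prev), 1e-300) < wtol)
      break
    prev <- f
  }
  km <- kmeans_restarts(t(state$V), c, seed = hp$seed + 1L,
                        n_restarts = hp$n_restarts)
  state$C <- t(km$centers)                # k x c
  state$G <- indicator_from_labels(km$cluster, c) * 0.8 + 0.2 / c
  state
}

# precompute masked-entry linear indices and their column ids so the
# imputation block touches only candidate entries
mask_index <- function(masks) {
  lapply(masks, function(m) {
    if (is.null(m)) return(NULL)
    ix <- which(m == 1)
    if (!length(ix)) return(NULL)
    list(ix = ix, col = ((ix - 1L) %/% nrow(m)) + 1L)
  })
}

# closed-form S block restricted to the masked entries (identical result to
# solve_imputation, without materializing full-matrix intermediates)
impute_step <- function(state, x, midx, u, eta) {
  for (i in seq_along(midx)) {
    mi <- midx[[i]]
    if (is.null(mi)) next
    uv <- (state$U[[i]] %*% state$V)[mi$ix]
    state$S[[i]][mi$ix] <-
      pmax(uv - x$omics[[i]]$values[mi$ix] - eta * u[[i]][mi$col] / 2, 0)
  }
  state
}

# repeat a single-block multiplicative step until the block stops moving
# (max-abs relative change <= 1e-6) or `cap` inner iterations; every inner
# step is individually non-increasing, so the composite is too
iterate_to_stationarity <- function(state, stepfun, block, cap) {
  blocks <- if (block %in% c("U", "Q", "S")) NULL else block
  for (j in seq_len(cap)) {
    before <- if (is.null(blocks)) state[[block]] else state[[blocks]]
    state <- stepfun(state)
    after <- if (is.null(blocks)) state[[block]] else state[[blocks]]
    delta <- if (is.list(after)) {
      max(mapply(function(a, b) max(abs(a - b)), after, before))
    } else max(abs(after - before))
    ref <- if (is.list(after)) max(vapply(after, function(a)
      max(abs(a)), numeric(1)), 1e-12) else max(abs(after), 1e-12)
    if (delta <= 1e-6 * ref) break
  }
  state
}

# hard run-time guard: the objective must never increase across a block
check_monotone <- function(prev, cur, f0, block) {
  if (cur > prev + 1e-8 * abs(f0) + 1e-12)
    stop("objective increased after block '", block, "' (", prev, " -> ",
         cur, "): update rule violated monotonicity")
  cur
}

#' Fit the joint factorization and cluster the cells
#'
#' Runs the full pipeline on an already-preprocessed dataset: dropout-
#' candidate detection and depth weights per omic, per-omic k-means
#' pseudo-labels, cell kNN graph, seeded initialization, then alternating
#' block updates (S, U, V, Q, C, G, alpha, in that order — alpha last so the
#' weights reflect the current blocks) until the relative objective change
#' drops below `tol` or `max_iter` is reached. The objective is re-evaluated
#' after every block and the fit aborts, naming the block, if it ever
#' increases beyond `1e-8 * |F0|` — monotone non-increase is a contract, not
#' a hope. Cluster labels are the column-wise argmax of the indicator matrix
#' `G` (ties broken toward the lowest cluster index). Identical seeds give
#' bitwise-identical results.
#'
#' @param x a [multi_omics] dataset; apply [preprocess_omics()] first if the
#'   values are raw counts.
#' @param c number of clusters (overrides `hp$c` when given).
#' @param hp a [plnmfg_hyperparameters()] object.
#' @param init optional partial initial state (a named list; any of `U`,
#'   `V`, `Q`, `S`, `C`, `G`, `alpha`) overriding the seeded defaults —
#'   mainly for controlled comparisons.
#' @param verbose print the per-iteration objective.
#' @return an object of class `plnmfg_fit`: `labels` (integer vector, 1..c),
#'   `state`, `history` (data.frame with the per-iteration objective and
#'   term breakdown), `alpha_trace`, `converged`, `iterations`, plus the
#'   pseudo-labels, graph, masks and depth weights used.
#' @export
plnmfg <- function(x, c = NULL, hp = plnmfg_hyperparameters(), init = NULL,
                   verbose = FALSE) {
  stopifnot(inherits(x, "multi_omics"))
  if (!is.null(c)) hp$c <- as.integer(c)
  if (is.null(hp$c)) stop("number of clusters `c` must be given")
  n <- n_cells(x)
  if (hp$c > n) stop("c must be <= n")
  if (is.null(hp$k)) hp$k <- hp$c
  if (hp$knn >= n) stop("knn must be < n")
  validate_hyperparameters(hp)
  v <- length(x$omics)
  # densify once: the alternating updates touch every entry every iteration
  for (i in seq_len(v))
    x$omics[[i]]$values <- as.matrix(x$omics[[i]]$values)
  impute <- rep_len(as.logical(hp$impute), v)

  # --- fixed preprocessing products -------------------------------------
  masks <- lapply(seq_len(v), function(i) {
    if (!impute[i])
      return(matrix(0, nrow(x$omics[[i]]$values), n))
    detect_dropout_candidates(x$omics[[i]], hp$dropout_threshold,
                              hp$dropout_method)
  })
  u <- lapply(x$omics, depth_weights)
  Yp <- lapply(seq_len(v), function(i)
    kmeans_pseudolabels(x$omics[[i]], hp$c, seed = hp$seed + i,
                        n_restarts = hp$n_restarts))
  Y <- lapply(Yp, `[[`, "Y")
  graph <- build_knn_graph(x, knn = hp$knn, metric = hp$graph_metric,
                           combine = hp$graph_combine)

  # --- state ------------------------------------------------------------
  state <- init_state(x, Y, hp, masks = masks, u = u, warmup = hp$warmup)
  if (!is.null(init))
    for (nm in intersect(names(init), names(state))) state[[nm]] <- init[[nm]]

  obj <- plnmfg_objective(state, x, Y, graph, u, hp)
  f0 <- as.numeric(obj)
  history <- list(rbind(c(iteration = 0, objective = f0, attr(obj, "terms"))))
  alpha_trace <- list(state$alpha)
  converged <- FALSE
  prev <- f0
  it <- 0L
  midx <- mask_index(masks)

  while (it < hp$max_iter) {
    it <- it + 1L
    cur <- prev
    if (any(vapply(midx, Negate(is.null), logical(1)))) {
      state <- impute_step(state, x, midx, u, hp$eta)
      cur <- check_monotone(cur,
        as.numeric(plnmfg_objective(state, x, Y, graph, u, hp)), f0, "S")
    }
    state <- iterate_to_stationarity(state, function(st) update_U(st, x, hp$floor),
                                     "U", hp$block_inner)
    cur <- check_monotone(cur,
      as.numeric(plnmfg_objective(state, x, Y, graph, u, hp)), f0, "U")
    state <- iterate_to_stationarity(state, function(st) update_V(st, x, Y, hp),
                                     "V", hp$block_inner)
    cur <- check_monotone(cur,
      as.numeric(plnmfg_objective(state, x, Y, graph, u, hp)), f0, "V")
    if (hp$delta > 0) {
      state <- iterate_to_stationarity(state, function(st) update_Q(st, Y, hp),
                                       "Q", hp$block_inner)
      cur <- check_monotone(cur,
        as.numeric(plnmfg_objective(state, x, Y, graph, u, hp)), f0, "Q")
    }
    if (hp$beta > 0 || hp$epsilon_graph > 0) {
      # equilibrate the cluster-structure pair: single multiplicative steps
      # leave C/G crawling between the centroid anchor and the graph
      # smoother, so the block is iterated to (approximate) stationarity
      for (j in seq_len(hp$cg_inner)) {
        if (hp$beta > 0) state <- update_C(state, hp)
        G_old <- state$G
        state <- update_G(state, graph, hp)
        if (max(abs(state$G - G_old)) <= 1e-6 * max(abs(G_old), 1e-12))
          break
      }
      cur <- check_monotone(cur,
        as.numeric(plnmfg_objective(state, x, Y, graph, u, hp)), f0, "CG")
    }
    if (v > 1) {
      f <- pmax(omic_costs(state, x, Y, u, hp), hp$floor)
      state$alpha <- update_alpha(f, hp$gamma)
      cur <- check_monotone(cur,
        as.numeric(plnmfg_objective(state, x, Y, graph, u, hp)), f0, "alpha")
    }
    obj <- plnmfg_objective(state, x, Y, graph, u, hp)
    history[[it + 1L]] <- rbind(c(iteration = it,
                                  objective = as.numeric(obj),
                                  attr(obj, "terms")))
    alpha_trace[[it + 1L]] <- state$alpha
    if (verbose)
      message(sprintf("iter %3d  objective %.6g", it, as.numeric(obj)))
    rel <- abs(prev - as.numeric(obj)) / max(abs(prev), 1e-300)
    prev <- as.numeric(obj)
    if (rel < hp$tol) { converged <- TRUE; break }
  }

  labels <- apply(state$G, 2L, which.max)   # which.max -> lowest index on ties
  structure(list(
    labels = as.integer(labels),
    cell_ids = x$cell_ids,
    state = state,
    history = as.data.frame(do.call(rbind, history)),
    alpha_trace = do.call(rbind, alpha_trace),
    converged = converged,
    iterations = it,
    hp = hp,
    pseudo_labels = Yp,
    graph = graph,
    masks = masks,
    depth_weights = u),
    class = "plnmfg_fit")
}

#' @export
print.plnmfg_fit <- function(x, ...) {
  cat("plnmfg fit: ", length(x$labels), " cells -> ", x$hp$c, " clusters\n",
      sep = "")
  cat("  iterations: ", x$iterations,
      if (x$converged) " (converged)" else " (max_iter reached)", "\n",
      sep = "")
  cat("  objective: ", utils::tail(x$history$objective, 1), "\n", sep = "")
  cat("  omic weights:", signif(x$state$alpha, 4), "\n")
  cat("  cluster sizes:", tabulate(x$labels, x$hp$c), "\n")
  invisible(x)
}
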