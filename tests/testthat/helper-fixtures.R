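# Fixture builders shared across test files. Everything is generated in
# code under explicit seeds; no data files.

# small random multi-omics dataset with strictly positive entries
random_dataset <- function(seed, v = 2, n = 12, d = c(8, 5)) {
  set.seed(seed)
  oms <- lapply(seq_len(v), function(i)
    omic_matrix(matrix(stats::runif(d[i] * n, 0.1, 2), d[i], n),
                name = paste0("om", i)))
  multi_omics(oms)
}

# random symmetric binary adjacency with zero diagonal
random_adjacency <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::rbinom(n * n, 1, p), n, n)
  A <- pmax(A, t(A))
  diag(A) <- 0
  A
}

# a complete random model instance: dataset, pseudo-labels, graph, depth
# weights, hyperparameters and a strictly positive state — the substrate
# for the per-block monotonicity checks
random_instance <- function(seed, v = 2, n = 12, d = c(8, 5), k = 3, c = 3,
                            eta = 1, beta = 0.5, delta = 0.5, eps = 0.5,
                            gamma = 2) {
  x <- random_dataset(seed, v, n, d)
  set.seed(seed + 1000L)
  Y <- lapply(seq_len(v), function(i)
    indicator_from_labels(sample(seq_len(c), n, replace = TRUE), c))
  graph <- graph_laplacian(random_adjacency(n, 0.3, seed + 2000L))
  u <- lapply(x$omics, depth_weights)
  masks <- lapply(seq_len(v), function(i) {
    m <- matrix(stats::rbinom(d[i] * n, 1, 0.3), d[i], n)
    x$omics[[i]]$values[m == 1] <<- 0      # masked entries must be zeros
    m
  })
  alpha <- stats::runif(v, 0.2, 1); alpha <- alpha / sum(alpha)
  state <- structure(list(
    U = lapply(seq_len(v), function(i) matrix(stats::runif(d[i] * k, 0.05, 1), d[i], k)),
    V = matrix(stats::runif(k * n, 0.05, 1), k, n),
    Q = lapply(seq_len(v), function(i) matrix(stats::runif(c * k, 0.05, 1), c, k)),
    S = lapply(seq_len(v), function(i) {
      S <- matrix(0, d[i], n)
      S[masks[[i]] == 1] <- stats::runif(sum(masks[[i]]), 0, 0.5)
      S
    }),
    C = matrix(stats::runif(k * c, 0.05, 1), k, c),
    G = matrix(stats::runif(c * n, 0.05, 1), c, n),
    alpha = alpha), class = "plnmfg_state")
  hp <- plnmfg_hyperparameters(beta = beta, delta = delta, eta = eta,
                               gamma = gamma, epsilon_graph = eps,
                               k = k, c = c, seed = seed)
  list(x = x, Y = Y, graph = graph, u = u, masks = masks, state = state,
       hp = hp)
}

objective_of <- function(inst, state = inst$state) {
  as.numeric(plnmfg_objective(state, inst$x, inst$Y, inst$graph, inst$u,
                              inst$hp))
}

# independent scalar minimizer on [lo, hi]: golden-section search (limited
# to ~sqrt(machine eps) by function flatness) followed by one exact
# parabolic refinement, valid because the objective is smooth (quadratic)
# wherever the minimizer is interior; boundary minima are clamped
golden_min <- function(f, lo = 0, hi = 10, tol = 1e-10) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  while (b - a > tol) {
    if (f(c1) < f(c2)) { b <- c2; c2 <- c1; c1 <- b - phi * (b - a) }
    else { a <- c1; c1 <- c2; c2 <- a + phi * (b - a) }
  }
  g <- (a + b) / 2
  # wide-spaced points avoid the cancellation that limits finite-difference
  # refinement; for a quadratic the fitted vertex is exact regardless of h
  h <- 0.25
  xs <- if (g - h >= lo) g + c(-h, 0, h) else lo + c(0, h, 2 * h)
  fs <- vapply(xs, f, numeric(1))
  den <- (xs[2] - xs[1]) * (fs[2] - fs[3]) -
    (xs[2] - xs[3]) * (fs[2] - fs[1])
  if (is.finite(den) && abs(den) > 0) {
    vert <- xs[2] - 0.5 * ((xs[2] - xs[1])^2 * (fs[2] - fs[3]) -
                             (xs[2] - xs[3])^2 * (fs[2] - fs[1])) / den
    vert <- min(max(vert, lo), hi)
    # accept the analytic vertex unless it is genuinely worse; last-bit
    # rounding of f must not veto it
    if (is.finite(vert) && f(vert) <= f(g) + 1e-12 * (1 + abs(f(g))))
      g <- vert
  }
  if (f(lo) < f(g)) g <- lo
  g
}

# preprocessed tiny-preset dataset + truth, silenced
tiny_fixture <- function(seed) {
  sim <- simulate_multiomics(sim_preset("tiny", seed = seed))
  x <- suppressMessages(suppressWarnings(preprocess_omics(sim$dataset)))
  list(x = x, truth = sim$truth$labels, sim = sim)
}
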