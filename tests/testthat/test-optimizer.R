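# objective evaluation, block updates, alpha closed form, fit behaviour

test_that("objective vanishes at an exact joint fit and matches scalars", {
  # hand-built consistent state: X = UV, Y = QV, V = CG, G constant
  n <- 4; k <- 2; c <- 2
  V <- matrix(1, k, n)
  U <- matrix(c(1, 2), 1, 2)
  X <- U %*% V                                   # 1 x n, all 3s
  x <- multi_omics(list(omic_matrix(X, name = "o")))
  Y <- list(matrix(0.5, c, n))
  Q <- matrix(0.25, c, k)                        # QV = 0.5 everywhere
  C <- matrix(1, k, c)                           # CG with G = 0.5: V = 1
  G <- matrix(0.5, c, n)
  st <- structure(list(U = list(U), V = V, Q = list(Q),
                       S = list(matrix(0, 1, n)), C = C, G = G, alpha = 1),
                  class = "plnmfg_state")
  hp <- plnmfg_hyperparameters(beta = 1, delta = 1, eta = 1,
                               epsilon_graph = 1, gamma = 2, k = k, c = c)
  g <- graph_laplacian(random_adjacency(n, 0.5, 1))
  obj <- plnmfg_objective(st, x, Y, g, list(rep(1, n)), hp)
  expect_equal(as.numeric(obj), 0, tolerance = 1e-12)

  # v = 1, alpha = 1, gamma = 2, X = 1, U = 1, V = 2, other weights 0
  x1 <- multi_omics(list(omic_matrix(matrix(1), name = "s")))
  st1 <- structure(list(U = list(matrix(1)), V = matrix(2),
                        Q = list(matrix(1)), S = list(matrix(0)),
                        C = matrix(1), G = matrix(1), alpha = 1),
                   class = "plnmfg_state")
  hp1 <- plnmfg_hyperparameters(beta = 0, delta = 0, eta = 0,
                                epsilon_graph = 0, gamma = 2, k = 1, c = 2)
  o1 <- plnmfg_objective(st1, x1, list(matrix(1)), NULL, list(1), hp1)
  expect_equal(as.numeric(o1), 1)
})

test_that("objective is strictly monotone in eta for nonzero S", {
  inst <- random_instance(17)
  o1 <- objective_of(inst)
  inst$hp$eta <- inst$hp$eta * 2
  expect_gt(objective_of(inst), o1)
})

test_that("each block update never increases the objective (oracle check)", {
  worst <- 0
  for (seed in 1:30) {
    inst <- random_instance(seed)
    base <- objective_of(inst)
    steps <- list(
      U = function(s) update_U(s, inst$x, inst$hp$floor),
      V = function(s) update_V(s, inst$x, inst$Y, inst$hp),
      Q = function(s) update_Q(s, inst$Y, inst$hp),
      C = function(s) update_C(s, inst$hp),
      G = function(s) update_G(s, inst$graph, inst$hp))
    for (nm in names(steps)) {
      after <- objective_of(inst, steps[[nm]](inst$state))
      expect_lte(after, base + 1e-8 * abs(base))
      worst <- max(worst, (after - base) / abs(base))
    }
    # S block: closed form must also not increase the full objective
    stS <- inst$state
    for (i in seq_along(inst$masks)) {
      R <- stS$U[[i]] %*% stS$V - as.matrix(inst$x$omics[[i]]$values)
      stS$S[[i]] <- solve_imputation(R, inst$masks[[i]], inst$u[[i]],
                                     inst$hp$eta)
    }
    expect_lte(objective_of(inst, stS), base + 1e-8 * abs(base))
  }
  expect_lte(worst, 1e-8)
})

test_that("updates are stationary at an exact factorization", {
  set.seed(77)
  k <- 2; n <- 5; d <- 4; c <- 2
  U <- matrix(stats::runif(d * k, 0.5, 1), d, k)
  V <- matrix(stats::runif(k * n, 0.5, 1), k, n)
  x <- multi_omics(list(omic_matrix(U %*% V, name = "e")))
  C <- matrix(stats::runif(k * c, 0.5, 1), k, c)
  G <- matrix(stats::runif(c * n, 0.5, 1), c, n)
  V <- C %*% G                             # V = CG exactly by construction
  x <- multi_omics(list(omic_matrix(U %*% V, name = "e")))
  Q <- matrix(stats::runif(c * k, 0.5, 1), c, k)
  Y <- list(Q %*% V)
  st <- structure(list(U = list(U), V = V, Q = list(Q),
                       S = list(matrix(0, d, n)), C = C, G = G, alpha = 1),
                  class = "plnmfg_state")
  hp <- plnmfg_hyperparameters(beta = 1, delta = 1, eta = 0,
                               epsilon_graph = 0, k = k, c = c)
  hp$floor <- 0                # exact stationarity needs no stabilizer
  stU <- update_U(st, x, 0)
  expect_equal(stU$U[[1]], U, tolerance = 1e-10)
  stQ <- update_Q(st, Y, hp)
  expect_equal(stQ$Q[[1]], Q, tolerance = 1e-10)
  stC <- update_C(st, hp)
  expect_equal(stC$C, C, tolerance = 1e-10)
  # a zero row of U is an absorbing state
  U0 <- U; U0[2, ] <- 0
  st0 <- st; st0$U <- list(U0)
  expect_equal(update_U(st0, x, 1e-10)$U[[1]][2, ], c(0, 0))
})

test_that("update_Q and update_G reduce to documented degenerate forms", {
  inst <- random_instance(5)
  hp0 <- inst$hp; hp0$delta <- 0
  expect_identical(update_Q(inst$state, inst$Y, hp0), inst$state)
  # empty graph and epsilon = 0 give the same G update
  hpe <- inst$hp; hpe$epsilon_graph <- 0
  g0 <- graph_laplacian(matrix(0, ncol(inst$state$G), ncol(inst$state$G)))
  G1 <- update_G(inst$state, g0, inst$hp)$G
  G2 <- update_G(inst$state, inst$graph, hpe)$G
  expect_equal(G1, G2, tolerance = 1e-12)
})

test_that("alpha closed form solves the simplex problem", {
  expect_equal(update_alpha(c(1, 4), 2), c(0.8, 0.2))
  expect_equal(update_alpha(c(3, 3), 2), c(0.5, 0.5))
  expect_equal(update_alpha(c(0, 2, 0), 2), c(0.5, 0, 0.5))
  # grid-search oracle at resolution 1e-3 on the 2-simplex
  set.seed(6)
  for (rep in 1:25) {
    f <- stats::runif(2, 0.1, 5)
    gamma <- stats::runif(1, 1.2, 5)
    grid <- seq(0.001, 0.999, by = 0.001)
    costs <- grid^gamma * f[1] + (1 - grid)^gamma * f[2]
    a_grid <- grid[which.min(costs)]
    a <- update_alpha(f, gamma)
    expect_lt(abs(a[1] - a_grid), 1e-3 + 1e-9)
    expect_equal(sum(a), 1, tolerance = 1e-12)
  }
})

test_that("fit reduces to classical multiplicative-update NMF", {
  set.seed(55)
  d <- 10; n <- 8; k <- 3
  X <- matrix(stats::runif(d * n, 0.2, 2), d, n)
  U0 <- matrix(stats::runif(d * k, 0.1, 1), d, k)
  V0 <- matrix(stats::runif(k * n, 0.1, 1), k, n)
  niter <- 25
  hp <- plnmfg_hyperparameters(beta = 0, delta = 0, eta = 0,
                               epsilon_graph = 0, impute = FALSE,
                               warmup = 0, block_inner = 1,
                               max_iter = niter, tol = 1e-300, seed = 9,
                               k = k, knn = 3)
  x <- multi_omics(list(omic_matrix(X, name = "nmf")))
  fit <- plnmfg(x, c = 2, hp = hp, init = list(U = list(U0), V = V0))
  # independent reference: classical alternating multiplicative updates
  U <- U0; V <- V0; fl <- hp$floor
  for (t in seq_len(niter)) {
    U <- U * (X %*% t(V)) / (U %*% V %*% t(V) + fl)
    V <- V * (t(U) %*% X) / (t(U) %*% U %*% V + fl)
  }
  err_ref <- sum((X - U %*% V)^2)
  err_fit <- sum((X - fit$state$U[[1]] %*% fit$state$V)^2)
  expect_equal(err_fit, err_ref, tolerance = 1e-6)
})

test_that("fit is deterministic, monotone, and recovers easy structure", {
  tf <- tiny_fixture(21)
  hp <- plnmfg_hyperparameters(seed = 4)
  f1 <- suppressWarnings(plnmfg(tf$x, c = 3, hp = hp))
  f2 <- suppressWarnings(plnmfg(tf$x, c = 3, hp = hp))
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$history$objective, f2$history$objective)
  obj <- f1$history$objective
  expect_true(all(diff(obj) <= 1e-8 * abs(obj[1])))
  # non-negativity and simplex constraints after the fit
  st <- f1$state
  expect_gte(min(st$V), 0); expect_gte(min(st$G), 0)
  expect_gte(min(st$C), 0)
  expect_true(all(vapply(st$U, min, numeric(1)) >= 0))
  expect_true(all(vapply(st$S, min, numeric(1)) >= 0))
  expect_equal(sum(st$alpha), 1, tolerance = 1e-12)
  expect_true(all(st$alpha > 0))
  # a clean, widely separated dataset is recovered perfectly
  sim <- simulate_multiomics(sim_preset("tiny", seed = 9, separation = 50,
                                        dropout_rate = 0))
  xx <- suppressMessages(suppressWarnings(preprocess_omics(sim$dataset)))
  fw <- suppressWarnings(plnmfg(xx, c = 3, hp = plnmfg_hyperparameters(seed = 2)))
  expect_equal(adjusted_rand_index(fw$labels, sim$truth$labels), 1)
})
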