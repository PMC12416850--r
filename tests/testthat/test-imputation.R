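# dropout-candidate detection, depth weights, closed-form S block

test_that("depth weights are library size normalized to mean 1", {
  m <- matrix(c(1, 0, 0, 3), 2, 2)   # libsizes 1 and 3
  u <- depth_weights(omic_matrix(m))
  expect_equal(u, c(0.5, 1.5))
  # uniform depth -> all ones; scale invariance
  eq <- omic_matrix(matrix(1, 3, 4))
  expect_equal(depth_weights(eq), rep(1, 4))
  expect_equal(depth_weights(omic_matrix(10 * m)), u)
  expect_error(depth_weights(omic_matrix(matrix(0, 2, 2))), "all-zero")
})

test_that("detection_rate scores follow the stated formula on a 2x2 toy", {
  # gene 1 detected in cell 2 only (rate 0.5); cell 1 has the smaller
  # library, rank fraction 0 -> score of the zero at (1,1) is 0.5
  m <- matrix(c(0, 1, 2, 3), 2, 2)
  om <- omic_matrix(m)
  expect_equal(detect_dropout_candidates(om, 0.4, "detection_rate")[1, 1], 1)
  expect_equal(detect_dropout_candidates(om, 0.5, "detection_rate")[1, 1], 0)
})

test_that("mask is confined to zeros and respects threshold extremes", {
  for (method in c("mixture", "detection_rate")) {
    set.seed(3)
    m <- matrix(stats::rbinom(300, 3, 0.4), 20, 15)
    om <- omic_matrix(m)
    mask <- detect_dropout_candidates(om, 0.2, method)
    expect_true(all(m[mask == 1] == 0))
    expect_equal(sum(detect_dropout_candidates(om, 1, method)), 0)
    dense <- omic_matrix(matrix(1, 4, 4))
    expect_equal(sum(detect_dropout_candidates(dense, 0, method)), 0)
  }
  expect_warning(
    mask0 <- detect_dropout_candidates(omic_matrix(matrix(0, 3, 3)), 0.5),
    "all-zero")
  expect_equal(sum(mask0), 0)
})

test_that("mixture scores decrease with cell depth", {
  set.seed(9)
  m <- matrix(stats::rbinom(600, 8, 0.5), 20, 30)
  m[, 1] <- m[, 1] * 0L               # shallowest: everything zero
  m[1, ] <- c(rep(0, 15), rep(4, 15)) # a half-detected gene
  om <- omic_matrix(m)
  sc <- detect_dropout_candidates(om, 0, "mixture")
  # the gene-1 zero in the all-zero (shallow) cell must be masked at a low
  # threshold while the same gene's zeros in deep cells score lower
  zf <- colMeans(m == 0)
  deep <- which(zf == min(zf))[1]
  expect_true(sc[1, 1] >= sc[1, deep])
})

test_that("solve_imputation is the entrywise soft-threshold minimizer", {
  # scalar worked case: residual 3, eta*u/2 = 1 -> S = 2
  S <- solve_imputation(matrix(3), matrix(1), u = 1, eta = 2)
  expect_equal(S[1, 1], 2)
  # unmasked positions stay zero no matter the residual
  S <- solve_imputation(matrix(5), matrix(0), u = 1, eta = 0)
  expect_equal(S[1, 1], 0)
  # eta = 0 is plain non-negative projection on the mask
  R <- matrix(c(-1, 2, 0.5, -3), 2, 2)
  M <- matrix(1, 2, 2)
  expect_equal(solve_imputation(R, M, u = c(1, 1), eta = 0), pmax(R, 0))
})

test_that("solve_imputation agrees with a golden-section minimizer", {
  set.seed(21)
  for (rep in 1:40) {
    r <- stats::runif(1, -2, 4)       # residual (UV - X) at one entry
    uj <- stats::runif(1, 0.2, 2)
    eta <- stats::runif(1, 0, 3)
    f <- function(s) (s - r)^2 + eta * uj * s
    s_star <- golden_min(f, 0, 10)
    s_pkg <- solve_imputation(matrix(r), matrix(1), uj, eta)[1, 1]
    expect_equal(s_pkg, s_star, tolerance = 1e-8)
  }
})

test_that("S block never worsens its objective and shrinks with eta", {
  set.seed(4)
  count_le <- 0L
  for (rep in 1:100) {
    d <- sample(2:6, 1); n <- sample(2:6, 1)
    R <- matrix(stats::runif(d * n, -1, 2), d, n)
    M <- matrix(stats::rbinom(d * n, 1, 0.5), d, n)
    u <- stats::runif(n, 0.3, 2); u <- u / mean(u)
    eta <- stats::runif(1, 0, 2)
    block_obj <- function(S) sum((S - R)^2) + eta * sum(u * colSums(abs(S)))
    S1 <- solve_imputation(R, M, u, eta)
    expect_lte(block_obj(S1), block_obj(matrix(0, d, n)) + 1e-12)
    # monotone in eta, elementwise
    S2 <- solve_imputation(R, M, u, eta + 0.5)
    expect_true(all(S2 <= S1 + 1e-12))
    count_le <- count_le + 1L
  }
  expect_equal(count_le, 100L)
})
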