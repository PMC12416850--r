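# External clustering-agreement metrics. Everything is computed from the
# predicted-vs-true contingency table; all four metrics are invariant to
# permutations of either labeling.

contingency_table <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  table(factor(pred), factor(truth))
}

#' Clustering accuracy by optimal cluster matching
#'
#' The maximum fraction of agreements over all injective mappings of
#' predicted clusters to true classes, solved exactly as a linear assignment
#' problem on the contingency table (Hungarian algorithm via
#' `clue::solve_LSAP`). Predicted and true cluster counts may differ; the
#' table is padded to square and unmatched clusters score 0.
#'
#' @param pred,truth label vectors of equal length (any label coding).
#' @return scalar in \[0, 1\]; 1 iff the partitions agree up to relabeling.
#' @export
clustering_accuracy <- function(pred, truth) {
  ct <- contingency_table(pred, truth)
  m <- max(dim(ct))
  sq <- matrix(0, m, m)
  sq[seq_len(nrow(ct)), seq_len(ncol(ct))] <- ct
  sol <- clue::solve_LSAP(sq, maximum = TRUE)
  unname(sum(sq[cbind(seq_len(m), sol)]) / length(pred))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement adjusted for chance under the permutation model;
#' 1 iff the partitions are identical up to relabeling, ~0 for independent
#' partitions (can be negative).
#'
#' @inheritParams clustering_accuracy
#' @return scalar <= 1.
#' @export
adjusted_rand_index <- function(pred, truth) {
  ct <- contingency_table(pred, truth)
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  a <- sum(choose(rowSums(ct), 2))
  b <- sum(choose(colSums(ct), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)       # both partitions degenerate
  unname((sum_ij - expected) / (max_index - expected))
}

entropy_from_counts <- function(cnt, n) {
  p <- cnt[cnt > 0] / n
  -sum(p * log(p))
}

mutual_info_from_table <- function(ct) {
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  mi <- 0
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) {
    nij <- ct[i, j]
    if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (a[i] * b[j]))
  }
  mi
}

#' Normalized mutual information
#'
#' Mutual information between the partitions normalized by the arithmetic
#' mean of the two label entropies (the most common convention). Both
#' partitions trivial (single cluster each) is treated as perfect agreement
#' (1); one trivial partition gives 0.
#'
#' @inheritParams clustering_accuracy
#' @return scalar in \[0, 1\].
#' @export
normalized_mutual_info <- function(pred, truth) {
  ct <- contingency_table(pred, truth)
  n <- sum(ct)
  h1 <- entropy_from_counts(rowSums(ct), n)
  h2 <- entropy_from_counts(colSums(ct), n)
  if (h1 == 0 && h2 == 0) return(1)
  denom <- (h1 + h2) / 2
  if (denom == 0) return(0)
  mi <- mutual_info_from_table(ct)
  unname(mi / denom)
}

# expected MI under the hypergeometric permutation model (Vinh et al.),
# in log space for numerical stability
expected_mutual_info <- function(ct) {
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  emi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    ai <- a[i]; bj <- b[j]
    lo <- max(ai + bj - n, 1)
    hi <- min(ai, bj)
    if (lo > hi) next
    for (nij in lo:hi) {
      term <- (nij / n) * log(n * nij / (ai * bj))
      lw <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
        lgamma(n - bj + 1) - lgamma(n + 1) - lgamma(nij + 1) -
        lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(n - ai - bj + nij + 1)
      emi <- emi + term * exp(lw)
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' Mutual information adjusted for chance by the permutation-model expected
#' MI and normalized by the arithmetic mean of the entropies:
#' `(MI - E[MI]) / (mean(H1, H2) - E[MI])`. ~0 for independent partitions,
#' 1 for identical ones.
#'
#' @inheritParams clustering_accuracy
#' @return scalar <= 1.
#' @export
adjusted_mutual_info <- function(pred, truth) {
  ct <- contingency_table(pred, truth)
  n <- sum(ct)
  h1 <- entropy_from_counts(rowSums(ct), n)
  h2 <- entropy_from_counts(colSums(ct), n)
  if (h1 == 0 && h2 == 0) return(1)
  mi <- mutual_info_from_table(ct)
  emi <- expected_mutual_info(ct)
  denom <- (h1 + h2) / 2 - emi
  if (denom == 0) return(0)
  unname((mi - emi) / denom)
}

#' All four clustering metrics at once
#'
#' @inheritParams clustering_accuracy
#' @return named list: `acc`, `ari`, `nmi`, `ami`.
#' @export
clustering_metrics <- function(pred, truth) {
  list(acc = clustering_accuracy(pred, truth),
       ari = adjusted_rand_index(pred, truth),
       nmi = normalized_mutual_info(pred, truth),
       ami = adjusted_mutual_info(pred, truth))
}
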