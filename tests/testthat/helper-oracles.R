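# Independent brute-force oracles used by both the metric unit tests and
# the acceptance checks.

perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# maximize agreement over all injective cluster mappings by enumeration
brute_acc <- function(pred, truth) {
  pu <- sort(unique(pred)); tu <- sort(unique(truth))
  m <- max(length(pu), length(tu))
  best <- 0
  for (p in perms_of(seq_len(m))) {
    map <- p[match(pred, pu)]
    best <- max(best, sum(map == match(truth, tu), na.rm = TRUE))
  }
  best / length(pred)
}

# ARI from explicit enumeration of all cell pairs
brute_ari <- function(pred, truth) {
  n <- length(pred)
  a <- b <- c2 <- d <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sp <- pred[i] == pred[j]; st <- truth[i] == truth[j]
    if (sp && st) a <- a + 1
    else if (sp && !st) b <- b + 1
    else if (!sp && st) c2 <- c2 + 1
    else d <- d + 1
  }
  tot <- a + b + c2 + d
  exp_idx <- (a + b) * (a + c2) / tot
  max_idx <- ((a + b) + (a + c2)) / 2
  if (max_idx == exp_idx) return(1)
  (a - exp_idx) / (max_idx - exp_idx)
}

# plug-in mutual information and entropy from label vectors
brute_mi <- function(p, t) {
  ct <- table(p, t); n <- sum(ct)
  mi <- 0
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct)))
    if (ct[i, j] > 0)
      mi <- mi + ct[i, j] / n *
        log(n * ct[i, j] / (sum(ct[i, ]) * sum(ct[, j])))
  mi
}

brute_entropy <- function(l) {
  p <- table(l) / length(l)
  -sum(p * log(p))
}

brute_nmi <- function(pred, truth) {
  h1 <- brute_entropy(pred); h2 <- brute_entropy(truth)
  if (h1 == 0 && h2 == 0) return(1)
  if (h1 + h2 == 0) return(0)
  brute_mi(pred, truth) / ((h1 + h2) / 2)
}
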