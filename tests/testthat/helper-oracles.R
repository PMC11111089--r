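# Independent oracles and small fixture builders shared across test files.

# Exact two-sided tail probability of the binary-trait score statistic
# S = sum(g * (y - mu)) by full enumeration of all 2^n case/control outcomes.
enum_score_pvalue <- function(s_obs, g, mu) {
  n <- length(g)
  stopifnot(n <= 14)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  pr <- apply(grid, 1, function(y) prod(ifelse(y == 1, mu, 1 - mu)))
  S <- drop(grid %*% g) - sum(g * mu)
  sum(pr[S >= abs(s_obs) - 1e-12]) + sum(pr[S <= -abs(s_obs) + 1e-12])
}

# All partitions of 1..n into exactly k nonempty groups (canonical labels).
all_partitions <- function(n, k) {
  out <- list()
  recurse <- function(labels, next_item, used) {
    if (next_item > n) {
      if (used == k) out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (g in seq_len(min(used + 1L, k)))
      recurse(c(labels, g), next_item + 1L, max(used, g))
  }
  recurse(integer(0), 1L, 0L)
  out
}

# Ward-style objective for a partition under dissimilarity d (matrix):
# sum over clusters of (1 / (2 * size)) * sum of within-cluster d^2.
ward_partition_cost <- function(labels, d) {
  cost <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    cost <- cost + sum(d[idx, idx, drop = FALSE]^2) / (2 * length(idx))
  }
  cost
}

# Random correlation-like PD matrix.
random_corr <- function(K, n = 50 * K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * K), n, K) %*% chol(0.4 * diag(K) + 0.6)
  stats::cor(X)
}

# T matrix with three planted row blocks in a hierarchy (blocks 1 and 2
# share part of their signal, block 3 is fully distinct), so every cut up
# to 3 has a unique stable solution. Most columns are null noise, keeping
# the perturbation variance (median column variance) at noise level.
planted_block_T <- function(K_per_block = 3, M = 400, n_signal = 20,
                            strength = 8, seed = 1) {
  set.seed(seed)
  K <- 3 * K_per_block
  Tm <- matrix(rnorm(K * M), K, M)
  rows <- function(b) (b - 1) * K_per_block + seq_len(K_per_block)
  Tm[rows(1), 1:n_signal] <- Tm[rows(1), 1:n_signal] + strength
  half <- n_signal %/% 2
  Tm[rows(2), seq_len(half)] <- Tm[rows(2), seq_len(half)] + strength
  Tm[rows(2), n_signal + seq_len(n_signal)] <-
    Tm[rows(2), n_signal + seq_len(n_signal)] + strength
  Tm[rows(3), 2 * n_signal + seq_len(n_signal)] <-
    Tm[rows(3), 2 * n_signal + seq_len(n_signal)] + strength
  list(T = Tm, labels = rep(1:3, each = K_per_block))
}
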