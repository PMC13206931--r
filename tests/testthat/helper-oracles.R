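# Independent oracles, deliberately written as plain loops so they share no
# code path with the package implementation.

# Brute-force TMM: hand-computed average ranks, explicit trim bounds,
# hand-accumulated weighted mean.
oracle_tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(counts)
  nonzero <- apply(counts, 1, function(r) any(r > 0))
  x <- counts[nonzero, , drop = FALSE]
  uq <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) uq[j] <- as.numeric(quantile(x[, j], 0.75)) / lib[j]
  ref <- which.min(abs(uq - mean(uq)))
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  f <- numeric(ncol(x))
  for (k in seq_len(ncol(x))) {
    obs <- x[, k]; rf <- x[, ref]
    ok <- obs > 0 & rf > 0
    obs <- obs[ok]; rf <- rf[ok]
    M <- log2(obs / lib[k]) - log2(rf / lib[ref])
    A <- (log2(obs / lib[k]) + log2(rf / lib[ref])) / 2
    w <- 1 / ((lib[k] - obs) / (lib[k] * obs) + (lib[ref] - rf) / (lib[ref] * rf))
    if (length(M) == 0 || max(abs(M)) < 1e-6) { f[k] <- 1; next }
    n <- length(M)
    rM <- avg_rank(M); rA <- avg_rank(A)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    num <- 0; den <- 0
    for (i in seq_len(n)) {
      if (rM[i] >= lo_m && rM[i] <= hi_m && rA[i] >= lo_a && rA[i] <= hi_a) {
        num <- num + M[i] * w[i]
        den <- den + w[i]
      }
    }
    f[k] <- 2^(num / den)
  }
  gm <- exp(mean(log(f)))
  f <- f / gm
  names(f) <- colnames(counts)
  f
}

# Hypergeometric upper tail by exhaustive enumeration of every size-n draw
# from a universe of N genes of which the first K belong to the term.
oracle_hyper_p <- function(N, K, n, k) {
  draws <- combn(N, n)
  hits <- 0L
  for (j in seq_len(ncol(draws))) if (sum(draws[, j] <= K) >= k) hits <- hits + 1L
  hits / ncol(draws)
}

# BH step-up by the hand formula q_(i) = min_{j>=i} p_(j)*m/j, clipped to 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    q_sorted[i] <- running
  }
  out <- numeric(m)
  out[o] <- pmin(q_sorted, 1)
  out
}

# NB count matrix for normalization tests.
random_nb_counts <- function(seed, n_genes = 50, depths = c(1, 1.4, 0.7),
                             dispersion = 0.1) {
  set.seed(seed)
  mu <- exp(rnorm(n_genes, 5, 1.5))
  x <- sapply(depths, function(d) rnbinom(n_genes, mu = mu * d, size = 1 / dispersion))
  dimnames(x) <- list(sprintf("g%03d", seq_len(n_genes)),
                      paste0("s", seq_along(depths)))
  x
}
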