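# Independent brute-force oracles used to cross-check the implementation.
# Each is written from the definition of the procedure, not from the code
# path it checks.

# Explicit trim-and-weight TMM: reference = sample whose upper-quartile
# CPM is closest to the mean; doubly trim M (30%) and A (5%) tails by
# rank; precision-weighted mean of surviving M; geometric mean 1.
oracle_tmm <- function(counts) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  fs <- sapply(seq_len(ncol(counts)), function(i) {
    obs <- counts[, i]; rf <- counts[, ref]
    nO <- lib[i]; nR <- lib[ref]
    M <- log2((obs / nO) / (rf / nR))
    A <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - rf) / nR / rf
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(M) >= loL & rank(M) <= hiL &
            rank(A) >= loS & rank(A) <= hiS
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  })
  unname(fs / exp(mean(log(fs))))
}

# Benjamini-Hochberg step-up from the definition: sort, multiply by n/i,
# enforce monotonicity from the largest p down, cap at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o] * n / seq_len(n)
  for (i in seq(n - 1, 1)) ps[i] <- min(ps[i], ps[i + 1])
  ps <- pmin(ps, 1)
  out <- numeric(n)
  out[o] <- ps
  out
}

# Kleinberg hub score by plain power iteration on the adjacency matrix.
oracle_hub_power <- function(adj, iters = 1000) {
  x <- rep(1, nrow(adj))
  for (i in seq_len(iters)) {
    x <- adj %*% x
    nx <- sqrt(sum(x^2))
    if (nx == 0) return(rep(0, nrow(adj)))
    x <- x / nx
  }
  as.numeric(x / max(x))
}

# Per-gene weighted least squares by explicit normal equations.
oracle_wls <- function(y, X, w) {
  solve(t(X) %*% (w * X), t(X) %*% (w * y))
}

# Pearson correlation from the explicit sum formula.
oracle_pearson <- function(a, b) {
  n <- length(a)
  (sum(a * b) - n * mean(a) * mean(b)) /
    sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
}
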