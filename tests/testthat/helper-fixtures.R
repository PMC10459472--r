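# Small programmatic fixtures shared across test files.

# A count matrix with named genes/samples and a 2-level (or more) grouping.
make_cm <- function(counts, groups = NULL, check_replicates = FALSE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  rn <- rownames(counts)
  if (is.null(rn) || anyDuplicated(rn) || any(rn == ""))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  cn <- colnames(counts)
  if (is.null(cn) || anyDuplicated(cn) || any(cn == ""))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (is.null(groups))
    groups <- rep(c("A", "B"), length.out = ncol(counts))
  count_matrix(counts, groups, check_replicates = check_replicates)
}

# Random NB counts in a 2-group design, no planted effect.
null_cm <- function(n_genes, n_per_group = 3, mu = 100, phi = 0.05, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  counts <- matrix(rnbinom(n_genes * n, mu = mu, size = 1 / phi), n_genes, n)
  make_cm(counts, rep(c("A", "B"), each = n_per_group))
}

# Gene profiles with planted correlated modules: each module shares a
# latent factor with loading `loading`; residual noise fills the rest of
# the unit variance. Module factors are orthogonalized so between-module
# correlation is ~0 (the planted separation), which otherwise fluctuates
# strongly with only a dozen samples. Returns a scaled expression_matrix.
module_profiles <- function(sizes, loading, n_samples = 12, seed = 1,
                            n_noise = 0) {
  set.seed(seed)
  n <- sum(sizes) + n_noise
  lab <- c(rep(seq_along(sizes), sizes), rep(0, n_noise))
  x <- matrix(rnorm(n * n_samples) * sqrt(1 - loading^2), n, n_samples)
  Z <- qr.Q(qr(matrix(rnorm(n_samples * length(sizes)), n_samples))) *
    sqrt(n_samples)
  for (m in seq_along(sizes)) {
    z <- Z[, m]
    x[lab == m, ] <- x[lab == m, , drop = FALSE] +
      loading * matrix(z, sum(lab == m), n_samples, byrow = TRUE)
  }
  rownames(x) <- paste0("g", seq_len(n))
  colnames(x) <- paste0("s", seq_len(n_samples))
  em <- expression_matrix(x, "ctf_cpm")
  list(em = scale_rows(em), truth = setNames(lab, rownames(x)))
}
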