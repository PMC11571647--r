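# Shared fixtures built in code.

# Standardized iid design matrix (n-1 variance convention, as the package
# standardizer produces).
std_design <- function(n, m, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  X <- apply(X, 2L, function(c) (c - mean(c)) / sd(c))
  colnames(X) <- sprintf("g%03d", seq_len(m))
  X
}

# Gene x sample matrix of two correlated blocks plus optional noise genes,
# from an explicit factor model (no counts layer) for network unit tests.
block_expr <- function(block_sizes, n, rho = 0.8, n_noise = 0, seed = 1) {
  set.seed(seed)
  lam <- sqrt(rho)
  rows <- list()
  for (k in seq_along(block_sizes)) {
    f <- rnorm(n)
    rows[[k]] <- t(sapply(seq_len(block_sizes[k]), function(i)
      lam * f + sqrt(1 - rho) * rnorm(n)))
  }
  if (n_noise > 0) rows[[length(rows) + 1L]] <- matrix(rnorm(n_noise * n),
                                                      n_noise, n)
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("gene_%04d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%03d", seq_len(n))
  m
}

# Small simulated dataset through the full counts pipeline; module sizes
# scale with the gene count so tiny fixtures stay valid.
small_sim <- function(seed = 1, n = 60, m = 120, p = 30, ...) {
  ms <- max(2L, as.integer(m %/% 4))
  simulate_dataset(sim_config(n_samples = n, m_genes = m, p_snps = p,
                              n_modules = 2L, module_sizes = c(ms, ms),
                              seed = seed, ...))
}

norm_log_expr <- function(sim) {
  log_transform(normalize_counts(sim$counts, size_factors(sim$counts)))
}

# Objective of the printed elastic-net criterion, computed independently of
# the solver (used by the objective-audit and oracle tests).
en_obj_ref <- function(X, y, mu, b, alpha, lambda) {
  r <- y - mu - drop(X %*% b)
  sum(r^2) + lambda * sum((1 - alpha) * b^2 + alpha * abs(b))
}
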