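# Independent oracles used across test files. These recompute quantities by
# a different route than the package code (explicit binary matrices, normal
# equations, exhaustive counting) so agreement is informative.

# stability recomputed from the full n x p binary selection matrix
nog_bruteforce <- function(subsets, p) {
  n <- length(subsets)
  Z <- matrix(0, n, p)
  for (j in seq_len(n)) Z[j, as.integer(subsets[[j]])] <- 1
  phat <- colMeans(Z)
  s2 <- n / (n - 1) * phat * (1 - phat)
  dbar <- mean(rowSums(Z))
  1 - mean(s2) / ((dbar / p) * (1 - dbar / p))
}

# OLS coefficients straight from the normal equations
ols_oracle <- function(X, y) {
  X1 <- cbind(1, X)
  drop(solve(crossprod(X1), crossprod(X1, y)))
}

# small genotype matrix with independent SNPs in HWE
toy_geno <- function(n, p, maf = 0.3, seed = 1) {
  set.seed(seed)
  g <- matrix(rbinom(n * p, 2, 1 - maf), n, p)  # counts of the major allele
  dimnames(g) <- list(sprintf("A%04d", seq_len(n)), sprintf("S%04d", seq_len(p)))
  storage.mode(g) <- "double"
  g
}

# simulate, QC-free, and return aligned genotype/adjusted-phenotype pair
sim_pair <- function(n, p, n_qtl, h2, seed, ld_rho = 0, n_farmbatch = 5) {
  cfg <- sim_config(n_samples = n, n_snps = p, n_qtl = n_qtl, h2 = h2,
                    ld_rho = ld_rho, n_farmbatch = n_farmbatch, seed = seed)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  prep <- prepare_phenotypes(sim$phenotypes)
  ok <- prep$retained
  y <- stats::setNames(prep$rfi_adj[ok], prep$animal_id[ok])
  list(geno = g[names(y), , drop = FALSE], y = y, truth = sim$truth,
       config = cfg)
}
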