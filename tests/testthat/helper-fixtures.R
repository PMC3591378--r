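# Shared fixtures and independent oracles.

# Three-locus toy panel: two SNPs and one haploid composite.
toy_loci <- function() {
  list(locus_def("snp1", "diploid_nuclear", c("A", "C")),
       locus_def("snp2", "diploid_nuclear", c("G", "T")),
       locus_def("mt", "haploid_composite", c("H1", "H2")))
}

toy_genotypes <- function() {
  genotype_table(data.frame(
    individual_id = c("f1", "f2"),
    length_mm = c(65, 70), mass_g = c(3.1, 3.9),
    snp1 = c("A/C", "C/A"), snp2 = c("G/G", "-"), mt = c("H1", "H2")),
    toy_loci())
}

# Two-population baseline over one biallelic SNP, given explicitly as counts.
tiny_baseline <- function() {
  counts <- data.frame(
    population = rep(c("p1", "p2"), each = 2),
    stock_group = rep(c("g1", "g2"), each = 2),
    locus = "snp1", allele = rep(c("A", "C"), 2),
    count = c(18, 2, 4, 16))
  baseline_set(counts, c(p1 = "g1", p2 = "g2"),
               list(locus_def("snp1", "diploid_nuclear", c("A", "C"))))
}

# Mixture of 4 fish over the tiny baseline's single SNP.
tiny_mixture <- function(calls = c("A/A", "A/C", "C/C", "A/C")) {
  genotype_table(data.frame(individual_id = paste0("m", seq_along(calls)),
                            snp1 = calls),
                 list(locus_def("snp1", "diploid_nuclear", c("A", "C"))))
}

# Explicit per-population frequencies for the tiny instance.
tiny_freqs <- function(pA = c(0.9, 0.2)) {
  list(p1 = list(snp1 = c(A = pA[1], C = 1 - pA[1])),
       p2 = list(snp1 = c(A = pA[2], C = 1 - pA[2])))
}

# Hardy-Weinberg likelihood of diploid calls at one biallelic SNP, computed
# through dbinom (counts the het 2pq factor via choose(2,1)) — an
# arithmetical path independent of the package's likelihood code.
hwe_lik <- function(call, pA) {
  nA <- sum(strsplit(call, "/", fixed = TRUE)[[1]] == "A")
  stats::dbinom(nA, 2, pA)
}

# Exhaustive-enumeration oracle for the fixed-frequency mixture model:
# for every origin configuration z in K^n, weight by the
# Dirichlet-multinomial marginal times the likelihood product, then read
# off posterior means of theta and of each z_i.
enumerate_posterior <- function(L, alpha) {
  n <- nrow(L); K <- ncol(L)
  configs <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  w <- apply(configs, 1, function(z) {
    counts <- tabulate(z, K)
    exp(sum(lgamma(alpha + counts))) * prod(L[cbind(seq_len(n), z)])
  })
  w <- w / sum(w)
  a0 <- sum(alpha)
  theta <- rep(0, K); zp <- matrix(0, n, K)
  for (r in seq_len(nrow(configs))) {
    z <- configs[r, ]
    theta <- theta + w[r] * (alpha + tabulate(z, K)) / (a0 + n)
    for (i in seq_len(n)) zp[i, z[i]] <- zp[i, z[i]] + w[r]
  }
  list(theta = theta, z_probs = zp)
}

# Normal-equations least-squares oracle: beta = (X'X)^{-1} X'y.
normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Small, fast synthetic design for MCMC-heavy tests.
small_design <- function(seed, differentiation = 0.1) {
  simulation_design(n_populations = 4L,
                    group_sizes = c(gA = 2L, gB = 2L),
                    n_diploid_loci = 20L, include_composites = FALSE,
                    differentiation = differentiation,
                    baseline_n_per_pop = 50L, seed = seed)
}

short_chains <- function(seed, n_chains = 2L) {
  chain_config(n_chains = n_chains, iterations = 2000L, thin = 2L,
               burn_in = 200L, seed = seed)
}
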