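# Shared study parameters for the analysis scripts. Everything is a pure
# function of these seeds, so each numbered script can regenerate the data
# it needs instead of passing binary state around.

library(gsimix)

SEED <- 2026L
RESULTS <- "results"

# Study-scale synthetic design: 13 baseline populations in three stock
# groups (5 Black Lake, 7 Chignik Lake, 1 Chignik River), 92 diploid SNPs
# plus one mtDNA-style haploid composite and one MHC-style phenotype
# composite, moderate differentiation.
design <- simulation_design(differentiation = 0.05, baseline_n_per_pop = 100L,
                            seed = SEED)

MIXTURE_N <- 200L
TRUE_PROPORTIONS <- c(BlackLake = 0.25, ChignikLake = 0.75, ChignikRiver = 0)

# Mixture chains: 3 randomized-start chains, thinned, half the retained
# draws discarded as burn-in.
mix_config <- chain_config(n_chains = 3L, iterations = 20000L, thin = 5L,
                           burn_in = 2000L, seed = SEED)

# Calibration replicates use a reduced single-chain configuration (a
# runtime, not correctness, matter; recorded in the report).
cal_config <- chain_config(n_chains = 1L, iterations = 3000L, thin = 2L,
                           burn_in = 500L, seed = SEED)

THRESHOLD_GRID <- seq(0.5, 0.9, by = 0.1)
REPORT_THRESHOLDS <- c(0.7, 0.8, 0.9)

simulated_data <- function() {
  base <- simulate_baseline(design)
  mix <- simulate_mixture(base$true_freqs, base$group_map, TRUE_PROPORTIONS,
                          n = MIXTURE_N, missing_rate = 0.002,
                          seed = SEED + 1L)
  # group-specific allometric lengths and masses, so condition analyses can
  # run on the same fish (measured to the mm and 0.1 g, as in the field)
  set.seed(SEED + 2L)
  g <- match(mix$truth$group, names(design$group_sizes))
  len <- rnorm(MIXTURE_N, c(69.7, 65.1, 66)[g], c(5.4, 7.9, 6)[g])
  while (any(len <= 0)) len[len <= 0] <- rnorm(sum(len <= 0), 66, 6)
  mass <- 10^(c(-5.00, -5.10, -5.05)[g] + 3.1 * log10(len) +
                rnorm(MIXTURE_N, 0, 0.04))
  df <- as.data.frame(mix$records)
  df$length_mm <- round(len)
  df$mass_g <- pmax(round(mass, 1), 0.1)
  mix$records <- genotype_table(df, table_loci(mix$records))
  list(base = base, mix = mix)
}

out_path <- function(...) {
  p <- file.path(RESULTS, ...)
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  p
}
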