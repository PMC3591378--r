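# gsimix

Bayesian genetic stock identification (GSI) for mixed-stock samples of SNP
genotypes, with holdout calibration of individual-assignment error rates and
AICc-based comparison of length–mass body-condition models. The package was
built around a juvenile sockeye salmon (*Oncorhynchus nerka*) study design —
a watershed where fish from a warm, productive natal lake emigrate
downstream into a colder lake and mix with the resident stock — but every
component is generic: any diploid SNP panel (plus composite haploid or
phenotype markers), any population-to-stock-group structure.

## What it computes

**Mixture allocation.** A mixture of `n` fish of unknown origin is
decomposed over `K` baseline populations by Gibbs sampling the
Pella–Masuda-style mixture model: for fish `i` with genotype `g_i`,

    z_i | θ      ~ Categorical(θ_1 L(g_i|p_1), …, θ_K L(g_i|p_K))   (normalized)
    θ | z        ~ Dirichlet(α + origin counts)
    p_k,ℓ | z    ~ Dirichlet(allele prior + baseline counts + counts of
                             mixture fish currently assigned to k)

where `L(g|p)` is the Hardy–Weinberg genotype likelihood (`p²`, `2pq`, or a
composite-category frequency) multiplied over loci, `α` defaults to the
uniform prior `1/K` per population, and the allele-frequency update (the
third line) can be switched off to condition on baseline posterior-mean
frequencies. Multiple randomized-start chains are pooled after burn-in;
convergence is checked with the Gelman–Rubin potential scale reduction
factor, and stock-group proportions are reported as posterior mean, median,
and the equal-tailed 95% credibility interval.

**Individual assignment and calibration.** Each fish's population-origin
probabilities are summed to stock-group probabilities; a fish is assigned to
its top group when that probability meets a threshold (default 80%),
otherwise it is `NOT_ASSIGNED`. The known-mixture holdout procedure draws a
test mixture from the baseline itself, rebuilds the baseline without those
fish, re-runs the full analysis, and scores per-group error rates
(1 − precision) and assigned fractions over a 50–90% threshold grid, across
replicates.

**Body condition.** Four nested regressions of log10 mass on log10 length —
shared intercept/slope, group intercepts, group slopes, or both — are
fitted by least squares on identical data and compared with
`AICc = n·ln(RSS/n) + 2k + 2k(k+1)/(n−k−1)` and Akaike weights
`w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2)`. Length distributions are compared with
ANOVA or Kruskal–Wallis, gated by Bartlett's variance test.

**Synthetic data.** Balding–Nichols baselines (ancestral frequencies
disturbed per population with concentration `(1−F)/F`), Hardy–Weinberg
genotypes, mixtures with known origins, and group-specific allometric
length–mass data — so the entire pipeline is testable without any external
genotype deposit.

## Worked example

```r
library(gsimix)

base <- simulate_baseline(simulation_design(differentiation = 0.05, seed = 2026))
mix  <- simulate_mixture(base$true_freqs, base$group_map,
                         c(0.25, 0.75, 0), n = 200, seed = 2027)
cfg  <- chain_config(n_chains = 3, iterations = 20000, thin = 5,
                     burn_in = 2000, seed = 2026)
draws <- run_chains(base$baseline, mix$records, config = cfg)
summarize_groups(draws)
```

On this seed the 200-fish mixture truly contains 50 Black Lake and 150
Chignik Lake fish, and the pooled posterior prints

```
         group   mean median   q2.5  q97.5 gelman_rubin converged
1    BlackLake 0.2634 0.2631 0.1995 0.3312       1.0000      TRUE
2  ChignikLake 0.7351 0.7354 0.6671 0.7993       1.0000      TRUE
3 ChignikRiver 0.0015 0.0000 0.0000 0.0143       1.0004      TRUE
```

— the 95% credibility intervals cover the true 25/75/0 composition, and the
Gelman–Rubin statistics sit at 1. Assigning individuals at the 80%
threshold (`assign_individuals(individual_posteriors(draws), 0.8)`) then
summarizing with `summarize_assignments()` gives the per-year sample
proportions by stock group, including the unassigned class.

The numbered scripts under `analysis/` run the full study workflow on
synthetic data (`01_simulate.R` → `04_condition.R`), writing tables under
`results/`; `run_pipeline()` does the same from a single YAML configuration
with a checksummed run manifest.

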