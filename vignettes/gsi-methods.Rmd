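---
title: "Methods: Bayesian stock identification, assignment calibration, and condition models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian stock identification, assignment calibration, and condition models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gsimix)
```

This vignette is the package's account of its statistical machinery: the
mixture model and its conditionals, the assignment and calibration
procedures, the condition-model comparison, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where more than one defensible option existed.

## The mixed-stock model

A mixture sample of $n$ genotyped individuals is modelled as draws from $K$
baseline populations with unknown proportions $\theta$. The joint model is

$$z_i \mid \theta \sim \mathrm{Categorical}(\theta), \qquad
g_i \mid z_i = k \sim \prod_\ell P(g_{i\ell} \mid p_{k\ell}),$$

with Hardy–Weinberg genotype probabilities per locus $\ell$: $p^2$ for a
diploid homozygote, $2pq$ for a heterozygote, and the raw category
frequency for composite haploid (joined mtDNA haplotype) or composite
phenotype (joint multi-locus genotype class) markers. Missing calls
contribute a factor of 1. The Gibbs sweep alternates

1. $z_i \sim$ categorical with weights $\theta_k L(g_i \mid p_k)$,
2. $\theta \sim \mathrm{Dirichlet}(\alpha + \text{origin counts})$,
3. optionally, $p_{k\ell} \sim \mathrm{Dirichlet}(\text{pseudocounts} +
   \text{baseline counts} + \text{counts from mixture fish with } z_i = k)$.

Step 3 is the full model and the default (`update_allele_freqs = TRUE`):
mixture fish currently assigned to a population sharpen its frequency
estimates, and baseline sampling noise propagates into the posterior. With
it off, frequencies are fixed at their baseline Dirichlet posterior means —
the conditional variant, useful for oracle testing (the posterior then has
a closed combinatorial form over origin configurations) and for very fast
calibration sweeps. Which variant the original BAYES analyses used is not
determinable from the study description, so both are provided.

**Priors.** The mixture prior defaults to $\alpha_k = 1/K$ — each pooled
baseline population equally weighted, parameters summing to one. Allele
pseudocounts default to $1/A_\ell$ per allele at a locus with $A_\ell$
alleles (the flat-total convention of this model family); a unit scheme is
available.

**Chains.** The reference configuration is 3 chains of 140{,}000
iterations, every 7th draw retained (20{,}000 per chain), and burn-in
interpreted as the first 10{,}000 *retained* draws per chain — i.e. half —
which is how the source description reads. Starts are randomized: three
random populations at proportion 0.3 and the remaining 0.1 split equally
(`"spiked"`), so chains approach the posterior from different corners of
the simplex; with $K < 4$ the scheme falls back to uniform with a warning.
Thinning is a plain configuration input here; the diagnostic originally
used to choose it is out of scope.

**Convergence.** Per stock group we report
$\hat R = \max\!\left(1, \sqrt{\tfrac{(n-1)W/n + B/n}{W}}\right)$ across
chains, with pass threshold 1.2 by default. The floor at 1 removes the
$(n-1)/n$ finite-sample deflation: duplicated chains give exactly 1, and
values below 1 carry no convergence information. The original "visual
assessment" is replaced by the exported draw tables, which plot directly.

**Numerics.** All likelihoods are accumulated in log space; categorical
sampling normalizes by the row maximum before exponentiating. When fixed
frequencies contain exact zeros, $\log 0$ is clamped to $-10^{10}$ inside
the matrix algebra (a genotype inadmissible in every population falls back
to sampling from $\theta$ alone, with a warning for all-missing fish).
Every random quantity derives from the user seed; chain $c$ uses a seed
derived from `(seed, c)`, so runs are bit-reproducible.

## Locus preprocessing

The preprocessing stage reproduces standard SNP-panel hygiene: failed-assay
loci are dropped; loci monomorphic across the pooled baseline are dropped
(mixture-only variation does not rescue a locus — the baseline carries no
information about it); the designated member of each linkage pair is
dropped; jointly inherited mtDNA SNPs are joined into one haploid composite
locus and the two MHC loci into one phenotype composite whose categories
are the *observed joint classes with empirical frequencies* — no
Hardy–Weinberg expansion across the pair, since the motivating treatment is
as a phenotypic character. A composite call is missing whenever any member
call is missing; inventing partial haplotypes seemed worse than discarding
one locus observation. Joint categories require individual-level baseline
genotypes (per-locus allele counts cannot be recombined into haplotype
classes), so composite construction errors on a counts-only baseline.

Individuals missing at least 15% of loci (inclusive, configurable) are
excluded after locus preprocessing.

## Individual assignment and holdout calibration

Population-origin posteriors are summed to stock-group probabilities; a
fish is assigned to its top group iff that probability is `>= threshold`
(inclusive: exactly 0.80 assigns at the 80% threshold). Thresholds from
0.5 up are accepted — only the arg-max group is ever considered, so the
assignment stays unique even at a 0.5 tie — and the evaluation grid runs
50–90% in steps of 10%.

Calibration follows the known-mixture design: draw a 200-fish test mixture
from the baseline with group totals matching the target proportions
(populations within a group drawn proportionally to their baseline sample
sizes, largest-remainder rounding), rebuild the baseline without those
fish, rerun the full MCMC and assignment, and score per group the error
rate (wrongly assigned among assigned to the group, i.e. 1 − precision)
and the assigned fraction. Means and SDs are taken over replicates; a
replicate in which nobody was assigned to a group leaves that error
undefined and it is excluded from the mean, with the count of contributing
replicates reported. Groups with target proportion zero contribute no
holdout fish but remain assignable — exactly the situation of a minor
stock that should attract no assignments. `choose_threshold()` returns the
smallest threshold whose mean error is below a ceiling (default 0.15) for
every group, the "assign as many as possible at acceptable error" rule.
Calibration replicates may use a deliberately reduced chain configuration;
chain length affects Monte-Carlo noise in the per-fish posteriors, not the
correctness of the scoring, and the configuration used is recorded in the
report.

## Condition models

Fish mass is regressed on length on the log10–log10 scale (the standard
allometric condition-factor analysis; natural log and untransformed
variants are exposed through a `transform` option, and the choice affects
coefficients, not the comparison machinery). The four candidate structures
share or split the intercept and slope between two groups:

| model | structure | k |
|---|---|---|
| `M_shared` | $B_0; B_1$ | 3 |
| `M_intercepts` | $B_{01}, B_{02}; B_1$ | 4 |
| `M_slopes` | $B_0; B_{11}, B_{12}$ | 4 |
| `M_full` | $B_{01}, B_{02}; B_{11}, B_{12}$ | 5 |

$k$ counts the residual variance as a parameter by default
(`count_sigma = TRUE`); the alternative convention shifts every $k$ by one,
which cancels from $\Delta$AICc only asymptotically, hence the flag.
Models are compared by
$\mathrm{AICc} = n\ln(\mathrm{RSS}/n) + 2k + 2k(k+1)/(n-k-1)$, with
$\Delta_i$ and Akaike weights computed jointly over the four fits on
identical data. Reported weights are rounded half-up to 2 decimals,
matching the presentation precision of the source tables.

Length comparisons are gated by Bartlett's test at $\alpha = 0.05$ (the
source states no level): homoscedastic groups go to one-way ANOVA, with
Tukey HSD pairwise comparisons when a third group (e.g. unassigned fish)
is present; heteroscedastic groups go to Kruskal–Wallis. A group with zero
length variance leaves Bartlett undefined and falls through to
Kruskal–Wallis with a note. Both between- and residual degrees of freedom
are reported, since published ANOVA tables are ambiguous about which
convention they print.

## The synthetic-data generator

The generator exists so that every stage is testable without the study's
genotype deposits. Its defaults mirror the study dimensions: 13 baseline
populations in stock groups of 5 (Black Lake), 7 (Chignik Lake) and
1 (Chignik River); 92 biallelic nuclear SNPs plus one 5-category haploid
composite and one 6-category phenotype composite; mixtures of 200 at
proportions 0.25/0.75/0.

Population structure is Balding–Nichols: ancestral diploid frequencies
uniform on (0.05, 0.95) — avoiding near-fixed, uninformative loci —
disturbed per population by a Beta/Dirichlet with concentration
$(1-F)/F$. The differentiation default $F = 0.05$ is in the range typical
of fine-scale salmon population structure within a watershed;
$F \to 0$ collapses all populations onto the ancestral frequencies.
Baseline sample sizes default to 100 fish per population, a realistic
collection size for managed salmon baselines. Genotypes are
Hardy–Weinberg draws; mixture fish get a group by the design proportions
(multinomially — realized compositions fluctuate, which is exactly what a
credibility interval should absorb), a population uniformly within the
group, and per-call missingness at rate 0.002, leaving roughly one fish in
six with at least one missing call on a 94-locus panel (the study-scale
analogue of its handful of high-missingness fish, which the 15% filter
then handles).

Length–mass data are generated per group from truncated-positive normal
lengths (defaults near the study's late-August juveniles: means 65–70 mm,
SDs 5–8 mm) and log-normal mass noise around a group allometry with
exponent ≈ 3.1 and residual SD 0.04 on the log10 scale (~10%
multiplicative noise).

What the generator does **not** emulate: linkage disequilibrium between
loci (the analysis drops LD pairs before inference), genotyping error,
age structure within the mixture, non-independent missingness, and any
ecological covariance between origin and condition beyond the configured
group allometries. Passing tests therefore demonstrate the statistical
machinery under the stated generative assumptions — not robustness to
violations real panels may show.

## Test and calibration scales

The test suite exercises the enumeration oracle (2 populations × 1 locus ×
4 fish, 200,000 post-burn-in draws, agreement within 0.01),
credibility-interval coverage at the full study design (20 replicates of
3 × 20,000-iteration chains thinned by 5; coverage of a boundary-true
proportion of 0 is scored with a 10⁻⁶ allowance on the lower interval end,
since continuous Dirichlet draws never place the empirical 2.5% quantile
at exactly zero), and holdout calibration at differentiation 0.02 vs 0.15
(10 replicates each, single reduced chains). These sizes are the package's
chosen trade-off between Monte-Carlo error and turnaround; all of them are
pure functions of fixed seeds.

## Known limitations

* Baseline pooling is taken as given; no inference about how populations
  should be grouped.
* No reversible-jump/model-averaging extensions of the mixture model.
* The conditional (fixed-frequency) variant ignores baseline sampling
  error; use the default full model when baseline sizes are modest.
* The composite-MHC treatment (joint observed genotype classes, empirical
  frequencies) is one defensible reading of "treat as phenotypic
  characters"; alternatives exist and would change composite-locus
  likelihoods.
* `choose_threshold()` treats an undefined error rate (no fish assigned to
  a group in any replicate) as non-blocking; a single stray assignment to
  a trace group can therefore raise the chosen threshold, which is visible
  in the replicate detail table.
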