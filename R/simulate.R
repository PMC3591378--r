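#' Design of a synthetic baseline
#'
#' Defaults mirror the Chignik-watershed study dimensions this package was
#' built around: 13 baseline populations in three stock groups (5 Black
#' Lake, 7 Chignik Lake, 1 Chignik River), 92 diploid nuclear SNPs, one
#' composite haploid mtDNA-style locus (5 categories), and one composite
#' MHC-style phenotype locus (6 categories).
#'
#' @param n_populations Number of baseline populations.
#' @param group_sizes Named integer vector of populations per stock group;
#'   must sum to `n_populations`.
#' @param n_diploid_loci Number of biallelic diploid loci.
#' @param include_composites Add one haploid composite and one phenotype
#'   composite locus.
#' @param n_haploid_categories,n_phenotype_categories Category counts for
#'   the two composite loci.
#' @param differentiation F-like parameter in (0, 1) controlling
#'   among-population allele-frequency spread (Balding-Nichols
#'   concentration `(1 - F) / F` around the ancestral frequency).
#' @param baseline_n_per_pop Individuals genotyped per baseline population.
#' @param seed Integer seed.
#' @return A `gsi_sim_design` list.
#' @export
simulation_design <- function(n_populations = 13L,
                              group_sizes = c(BlackLake = 5L,
                                              ChignikLake = 7L,
                                              ChignikRiver = 1L),
                              n_diploid_loci = 92L,
                              include_composites = TRUE,
                              n_haploid_categories = 5L,
                              n_phenotype_categories = 6L,
                              differentiation = 0.05,
                              baseline_n_per_pop = 100L,
                              seed = 1L) {
  stopifnot(sum(group_sizes) == n_populations,
            differentiation > 0, differentiation < 1,
            baseline_n_per_pop >= 1L, n_diploid_loci >= 1L)
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- paste0("group_", seq_along(group_sizes))
  }
  structure(list(n_populations = as.integer(n_populations),
                 group_sizes = group_sizes,
                 n_diploid_loci = as.integer(n_diploid_loci),
                 include_composites = isTRUE(include_composites),
                 n_haploid_categories = as.integer(n_haploid_categories),
                 n_phenotype_categories = as.integer(n_phenotype_categories),
                 differentiation = differentiation,
                 baseline_n_per_pop = as.integer(baseline_n_per_pop),
                 seed = as.integer(seed)),
            class = "gsi_sim_design")
}

sim_loci <- function(design) {
  loci <- lapply(seq_len(design$n_diploid_loci), function(j) {
    locus_def(sprintf("L%03d", j), "diploid_nuclear", c("A", "C"))
  })
  if (design$include_composites) {
    loci <- c(loci,
              list(locus_def("mtComposite", "haploid_composite",
                             paste0("H", seq_len(design$n_haploid_categories))),
                   locus_def("MHCcomposite", "phenotype_composite",
                             paste0("P", seq_len(design$n_phenotype_categories)))))
  }
  names(loci) <- locus_names(loci)
  loci
}

# One Dirichlet draw centered on `center` with Balding-Nichols
# concentration (1-F)/F.
rdirichlet_bn <- function(center, F) {
  g <- stats::rgamma(length(center), shape = center * (1 - F) / F)
  if (sum(g) == 0) g[which.max(center)] <- 1
  g / sum(g)
}

#' Simulate a baseline with known allele frequencies
#'
#' Ancestral allele frequencies are drawn uniform on (0.05, 0.95) per
#' diploid locus (uniform on the simplex for composite categories);
#' population frequencies are drawn from a Beta/Dirichlet centered on the
#' ancestral value with concentration `(1 - F) / F` (Balding-Nichols
#' structure); baseline individuals are then sampled from their
#' population's frequencies under Hardy-Weinberg. Reproducible from the
#' design seed.
#'
#' @param design A [simulation_design()].
#' @return List with `baseline` (a [baseline_set()] carrying the simulated
#'   individuals), `true_freqs` (per population, per locus, named
#'   frequency vectors), and `group_map`.
#' @export
simulate_baseline <- function(design = simulation_design()) {
  stopifnot(inherits(design, "gsi_sim_design"))
  set.seed(design$seed)
  loci <- sim_loci(design)
  groups <- names(design$group_sizes)
  pops <- unlist(lapply(seq_along(groups), function(g) {
    sprintf("%s_p%d", groups[g], seq_len(design$group_sizes[g]))
  }))
  group_map <- stats::setNames(rep(groups, design$group_sizes), pops)
  F <- design$differentiation

  ancestral <- lapply(loci, function(locus) {
    if (is_diploid(locus)) {
      p <- stats::runif(1, 0.05, 0.95)
      stats::setNames(c(p, 1 - p), locus$alleles)
    } else {
      g <- stats::rgamma(length(locus$alleles), 1)
      stats::setNames(g / sum(g), locus$alleles)
    }
  })
  true_freqs <- lapply(stats::setNames(pops, pops), function(pop) {
    lapply(ancestral, function(a) {
      stats::setNames(rdirichlet_bn(unname(a), F), names(a))
    })
  })

  n <- design$baseline_n_per_pop
  tabs <- lapply(pops, function(pop) {
    df <- data.frame(individual_id = sprintf("%s_i%04d", pop, seq_len(n)),
                     population = pop)
    for (ln in names(loci)) {
      df[[ln]] <- draw_calls(loci[[ln]], true_freqs[[pop]][[ln]], n)
    }
    df
  })
  individuals <- genotype_table(do.call(rbind, tabs), loci)
  baseline <- baseline_from_individuals(individuals, group_map)
  attr(true_freqs, "loci") <- loci
  list(baseline = baseline, true_freqs = true_freqs, group_map = group_map)
}

draw_calls <- function(locus, freqs, n) {
  a <- names(freqs)
  if (is_diploid(locus)) {
    a1 <- sample(a, n, replace = TRUE, prob = freqs)
    a2 <- sample(a, n, replace = TRUE, prob = freqs)
    paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  } else {
    sample(a, n, replace = TRUE, prob = freqs)
  }
}

#' Simulate a mixture of known origin
#'
#' Each fish's stock group is drawn from `group_proportions`, its
#' population uniformly within the group, and its genotype from that
#' population's true frequencies under Hardy-Weinberg. Each call is then
#' independently set missing with probability `missing_rate`.
#'
#' @param true_freqs Per-population frequency list from
#'   [simulate_baseline()].
#' @param group_map Named map `population -> group` from
#'   [simulate_baseline()].
#' @param group_proportions Proportions per stock group (in `group_map`
#'   group order, or named), summing to 1.
#' @param n Mixture size.
#' @param missing_rate Per-call missingness probability (default 0.002,
#'   which leaves roughly one fish in six carrying at least one missing
#'   call on a 94-locus panel).
#' @param seed Integer seed.
#' @return List with `records` (a [genotype_table()]) and `truth` (data
#'   frame `individual_id, population, group`).
#' @export
simulate_mixture <- function(true_freqs, group_map, group_proportions,
                             n = 200L, missing_rate = 0.002, seed = 1L) {
  set.seed(seed)
  groups <- unique(unname(group_map))
  if (!is.null(names(group_proportions))) {
    group_proportions <- group_proportions[groups]
  }
  stopifnot(length(group_proportions) == length(groups),
            abs(sum(group_proportions) - 1) < 1e-8,
            missing_rate >= 0, missing_rate < 1)
  pops <- names(group_map)
  first <- true_freqs[[1]]

  fish_group <- sample(groups, n, replace = TRUE, prob = group_proportions)
  fish_pop <- vapply(fish_group, function(g) {
    cand <- pops[group_map == g]
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }, character(1), USE.NAMES = FALSE)

  df <- data.frame(individual_id = sprintf("mix_%04d", seq_len(n)))
  loci_defs <- attr(true_freqs, "loci")
  if (is.null(loci_defs)) {
    # frequencies supplied without locus definitions: treat every locus
    # with a 2-symbol alphabet of single characters as diploid
    loci_defs <- lapply(names(first), function(ln) {
      a <- names(first[[ln]])
      mode <- if (length(a) == 2L && all(nchar(a) == 1L)) "diploid_nuclear"
              else "haploid_composite"
      locus_def(ln, mode, a)
    })
    names(loci_defs) <- names(first)
  }
  for (ln in names(first)) {
    calls <- character(n)
    for (pop in unique(fish_pop)) {
      idx <- fish_pop == pop
      calls[idx] <- draw_calls(loci_defs[[ln]], true_freqs[[pop]][[ln]],
                               sum(idx))
    }
    if (missing_rate > 0) {
      calls[stats::runif(n) < missing_rate] <- NA_character_
    }
    df[[ln]] <- calls
  }
  list(records = genotype_table(df, loci_defs),
       truth = data.frame(individual_id = df$individual_id,
                          population = fish_pop, group = fish_group))
}

#' Design of a synthetic length-mass dataset
#'
#' Per group: an allometric intercept and slope on the chosen log scale, a
#' residual SD of log mass, and a (truncated-positive) normal length
#' distribution. Defaults emulate late-August juvenile sockeye: mean fork
#' lengths near 65-70 mm with SDs of 5-8 mm, allometric exponent near 3.1,
#' and ~10% multiplicative mass noise.
#'
#' @param groups Group names.
#' @param intercept,slope Per-group allometric coefficients on the
#'   `transform` scale (mass in g on length in mm).
#' @param resid_sd Per-group residual SD of transformed mass.
#' @param length_mean,length_sd Per-group fork-length distribution (mm).
#' @param n Per-group sample sizes.
#' @param transform `"log10"` (default), `"ln"`, or `"none"`.
#' @param seed Integer seed.
#' @return A `gsi_condition_design` list.
#' @export
condition_design <- function(groups = c("BlackLake_residents",
                                        "ChignikLake_residents"),
                             intercept = c(-5.05, -5.20),
                             slope = c(3.10, 3.13),
                             resid_sd = c(0.04, 0.04),
                             length_mean = c(69.7, 65.1),
                             length_sd = c(5.4, 7.9),
                             n = c(200L, 416L),
                             transform = "log10", seed = 1L) {
  g <- length(groups)
  stopifnot(length(intercept) == g, length(slope) == g,
            length(resid_sd) == g, all(resid_sd >= 0),
            length(length_mean) == g, length(length_sd) == g,
            length(n) == g, all(n >= 1))
  structure(list(groups = groups, intercept = intercept, slope = slope,
                 resid_sd = resid_sd, length_mean = length_mean,
                 length_sd = length_sd, n = as.integer(n),
                 transform = transform, seed = as.integer(seed)),
            class = "gsi_condition_design")
}

#' Simulate a length-mass dataset
#'
#' Lengths are drawn normal per group, truncated to be positive; the
#' transformed mass is `intercept + slope * transform(length) + noise`
#' with normal noise of the design's residual SD.
#'
#' @param design A [condition_design()].
#' @return A [condition_data()].
#' @export
simulate_condition <- function(design = condition_design()) {
  stopifnot(inherits(design, "gsi_condition_design"))
  set.seed(design$seed)
  f <- transform_fun(design$transform)
  inv <- switch(design$transform, log10 = function(x) 10^x, ln = exp,
                none = identity)
  parts <- lapply(seq_along(design$groups), function(g) {
    n <- design$n[g]
    len <- stats::rnorm(n, design$length_mean[g], design$length_sd[g])
    while (any(len <= 0)) {
      len[len <= 0] <- stats::rnorm(sum(len <= 0), design$length_mean[g],
                                    design$length_sd[g])
    }
    y <- design$intercept[g] + design$slope[g] * f(len) +
      stats::rnorm(n, 0, design$resid_sd[g])
    data.frame(group = design$groups[g], length_mm = len, mass_g = inv(y))
  })
  d <- do.call(rbind, parts)
  condition_data(d$group, d$length_mm, d$mass_g)
}
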