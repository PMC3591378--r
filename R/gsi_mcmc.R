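#' Prior specification for the mixed-stock model
#'
#' @param mixture_prior Dirichlet parameter vector over the K baseline
#'   populations, all entries > 0. Default `NULL` means the uniform prior
#'   with each population given equal weight and the parameters summing to
#'   one (each `1/K`).
#' @param allele_prior_scheme Rule producing per-locus Dirichlet
#'   pseudocounts for allele frequencies: `"flat_total"` (default) gives
#'   `1/A_l` per allele at a locus with `A_l` alleles; `"unit"` gives 1 per
#'   allele.
#' @return A `gsi_prior` object.
#' @export
prior_spec <- function(mixture_prior = NULL,
                       allele_prior_scheme = c("flat_total", "unit")) {
  allele_prior_scheme <- match.arg(allele_prior_scheme)
  if (!is.null(mixture_prior) && any(mixture_prior <= 0)) {
    stop("mixture prior parameters must be > 0", call. = FALSE)
  }
  structure(list(mixture_prior = mixture_prior,
                 allele_prior_scheme = allele_prior_scheme),
            class = "gsi_prior")
}

#' Chain configuration
#'
#' @param n_chains Number of independent chains (default 3).
#' @param iterations Gibbs iterations per chain (default 140000).
#' @param thin Retain every `thin`-th draw (default 7).
#' @param burn_in Retained (thinned) draws discarded per chain before
#'   pooling (default 10000). `iterations / thin` must be an integer at
#'   least `burn_in`.
#' @param seed Integer seed; all chain randomness derives from it.
#' @param start_scheme `"spiked"` (default): starting proportions of 0.3
#'   randomly assigned to 3 populations and the remaining 0.1 divided among
#'   all others; `"uniform"`: equal starting proportions.
#' @param update_allele_freqs If `TRUE` (default, the full model),
#'   population allele frequencies are resampled each sweep conditioned on
#'   baseline counts plus mixture fish currently assigned to the
#'   population; if `FALSE`, frequencies are fixed at their baseline
#'   posterior means.
#' @param gr_threshold Gelman-Rubin pass threshold (default 1.2).
#' @return A `gsi_chain_config` object.
#' @export
chain_config <- function(n_chains = 3L, iterations = 140000L, thin = 7L,
                         burn_in = 10000L, seed = 1L,
                         start_scheme = c("spiked", "uniform"),
                         update_allele_freqs = TRUE, gr_threshold = 1.2) {
  start_scheme <- match.arg(start_scheme)
  stopifnot(n_chains >= 1L, iterations >= 1L, thin >= 1L, burn_in >= 0L)
  n_ret <- iterations / thin
  if (n_ret != round(n_ret) || n_ret < burn_in) {
    stop("iterations/thin must be an integer >= burn_in", call. = FALSE)
  }
  structure(list(n_chains = as.integer(n_chains),
                 iterations = as.integer(iterations), thin = as.integer(thin),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 start_scheme = start_scheme,
                 update_allele_freqs = isTRUE(update_allele_freqs),
                 gr_threshold = gr_threshold),
            class = "gsi_chain_config")
}

#' Genotype log-likelihood under one population's frequencies
#'
#' Sum over non-missing loci of the Hardy-Weinberg genotype log-probability:
#' `log(p^2)` for a diploid homozygote, `log(2pq)` for a heterozygote, and
#' the log category frequency for haploid/phenotype composite loci. Missing
#' loci contribute 0. An observed allele with frequency 0 yields `-Inf`.
#'
#' @param record A one-row [genotype_table()] (or a row of one).
#' @param pop_freqs Named list per locus of named allele-frequency vectors
#'   (each summing to 1), e.g. one population's element of
#'   [baseline_posterior_freqs()].
#' @return Log-probability (possibly `-Inf`).
#' @export
genotype_log_likelihood <- function(record, pop_freqs) {
  stopifnot(inherits(record, "gsi_genotypes"), nrow(record) == 1L)
  loci <- table_loci(record)
  ll <- 0
  for (ln in names(loci)) {
    call <- record[[ln]]
    if (is.na(call)) next
    f <- pop_freqs[[ln]]
    if (is.null(f)) stop("no frequencies for locus '", ln, "'", call. = FALSE)
    if (is_diploid(loci[[ln]])) {
      a <- call_alleles(call)
      p <- unname(f[a[1]]); q <- unname(f[a[2]])
      term <- if (a[1] == a[2]) 2 * log(p) else log(2) + log(p) + log(q)
    } else {
      term <- log(unname(f[call]))
    }
    ll <- ll + term
  }
  ll
}

#' Starting stock proportions for one chain
#'
#' Under the `"spiked"` scheme, three distinct randomly chosen populations
#' receive starting proportion 0.3 and the remaining 0.1 is divided equally
#' among all other populations, so different chains start from different
#' corners of the simplex. Requires K >= 4; smaller K falls back to a
#' uniform start with a warning.
#'
#' @param K Number of baseline populations.
#' @param scheme `"spiked"` or `"uniform"`.
#' @return A K-vector summing to 1.
#' @export
initial_theta <- function(K, scheme = c("spiked", "uniform")) {
  scheme <- match.arg(scheme)
  if (scheme == "uniform") return(rep(1 / K, K))
  if (K < 4L) {
    warning("spiked start needs K >= 4; using uniform start")
    return(rep(1 / K, K))
  }
  theta <- rep(0.1 / (K - 3), K)
  theta[sample.int(K, 3L)] <- 0.3
  theta
}

# Shared setup for one mixture analysis: encodings and prior count matrix.
mcmc_inputs <- function(baseline, mixture, prior, freqs = NULL) {
  if (!setequal(names(baseline$loci), names(table_loci(mixture)))) {
    stop("baseline and mixture loci differ", call. = FALSE)
  }
  layout <- allele_layout(baseline$loci)
  X <- encode_genotypes(mixture, layout)
  if (any(attr(X, "n_obs") == 0L)) {
    warning("individual(s) with all loci missing are assigned by prior ",
            "alone: ",
            paste(mixture$individual_id[attr(X, "n_obs") == 0L],
                  collapse = ", "))
  }
  B <- baseline_count_matrix(baseline, layout)
  pc <- B + allele_pseudocounts(layout, prior$allele_prior_scheme)
  K <- length(baseline$populations)
  alpha <- prior$mixture_prior %||% rep(1 / K, K)
  if (length(alpha) != K) stop("mixture prior length != K", call. = FALSE)
  P <- if (is.null(freqs)) normalize_blocks(pc, layout) else
    freqs_to_matrix(freqs, layout)
  logP <- log(P)
  logP[is.infinite(logP)] <- -1e10  # zero frequency: effectively impossible
  list(layout = layout, X = X, prior_counts = pc, logP = logP, alpha = alpha,
       K = K)
}

#' Run one Gibbs chain
#'
#' One sweep per iteration: (1) each latent origin `z_i` is drawn from the
#' categorical distribution proportional to `theta_k * L(g_i | p_k)`;
#' (2) `theta` is drawn from `Dirichlet(mixture prior + origin counts)`;
#' (3) if allele-frequency updating is on, each population-locus frequency
#' vector is drawn from `Dirichlet(pseudocounts + baseline counts + allele
#' counts of mixture fish currently assigned to the population)`, otherwise
#' frequencies stay at their baseline posterior means. Every `thin`-th draw
#' is retained. Reproducible given `(seed, chain_index)`.
#'
#' @param baseline A [baseline_set()].
#' @param mixture A [genotype_table()] sharing the baseline's loci.
#' @param prior A [prior_spec()].
#' @param config A [chain_config()].
#' @param chain_index Which chain this is (drives the chain's seed/start).
#' @param freqs Optional explicit per-population frequencies (format of
#'   [baseline_posterior_freqs()]) used when `update_allele_freqs` is off.
#' @return List with `theta` (retained draws x K matrix, populations as
#'   columns) and `zcount` (n x K tally of origins over post-burn-in
#'   retained draws).
#' @export
run_chain <- function(baseline, mixture, prior = prior_spec(),
                      config = chain_config(), chain_index = 1L,
                      freqs = NULL) {
  inp <- mcmc_inputs(baseline, mixture, prior, freqs)
  set.seed(chain_seed(config$seed, chain_index))
  theta0 <- initial_theta(inp$K, config$start_scheme)
  res <- gibbs_gsi_cpp(inp$X, inp$prior_counts, inp$logP,
                       inp$layout$block - 1L, inp$layout$n_loci,
                       inp$alpha, theta0,
                       config$iterations, config$thin, config$burn_in,
                       config$update_allele_freqs)
  colnames(res$theta) <- baseline$populations
  colnames(res$zcount) <- baseline$populations
  res
}

chain_seed <- function(seed, chain_index) {
  (as.double(seed) * 1009 + 97 * as.double(chain_index)) %% 2147483587 + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run all chains and pool the posterior
#'
#' Runs `config$n_chains` independent chains with distinct randomized
#' starts, removes `config$burn_in` retained draws per chain, and pools the
#' remainder. Per-individual origin probabilities (`z_probs`) are the
#' pooled post-burn-in origin frequencies.
#'
#' @inheritParams run_chain
#' @return A `gsi_posterior` object: `theta` (list of per-chain retained
#'   draw matrices, burn-in still attached), `z_probs` (n x K), plus the
#'   population/group bookkeeping and the configuration used.
#' @export
run_chains <- function(baseline, mixture, prior = prior_spec(),
                       config = chain_config(), freqs = NULL) {
  chains <- lapply(seq_len(config$n_chains), function(ci) {
    run_chain(baseline, mixture, prior, config, chain_index = ci,
              freqs = freqs)
  })
  zcount <- Reduce(`+`, lapply(chains, `[[`, "zcount"))
  z_probs <- zcount / pmax(rowSums(zcount), 1)
  rownames(z_probs) <- mixture$individual_id
  structure(list(theta = lapply(chains, `[[`, "theta"),
                 z_probs = z_probs,
                 populations = baseline$populations,
                 group_map = baseline$group_map,
                 group_levels = baseline$group_levels,
                 individual_id = mixture$individual_id,
                 config = config),
            class = "gsi_posterior")
}

#' @export
print.gsi_posterior <- function(x, ...) {
  cat(sprintf(
    "<gsi_posterior> %d chains x %d retained draws (burn-in %d), %d pops, %d fish\n",
    length(x$theta), nrow(x$theta[[1]]), x$config$burn_in,
    length(x$populations), nrow(x$z_probs)))
  invisible(x)
}

# Per-chain post-burn-in stock-group proportion series (draws x groups).
group_series <- function(draws) {
  G <- outer(unname(draws$group_map[draws$populations]), draws$group_levels,
             `==`) * 1
  lapply(draws$theta, function(th) {
    post <- th[(draws$config$burn_in + 1):nrow(th), , drop = FALSE]
    out <- post %*% G
    colnames(out) <- draws$group_levels
    out
  })
}

#' Gelman-Rubin potential scale reduction factor
#'
#' `sqrt((((n-1)/n) * W + B/n) / W)` from the between-chain variance `B`
#' and within-chain variance `W`, floored at 1 (the raw ratio dips below 1
#' by the finite-sample factor `(n-1)/n` when chains agree; values below 1
#' carry no convergence information). Two identical chains therefore give
#' exactly 1; if both `B` and `W` are zero the statistic is defined as 1.
#'
#' @param series A numeric matrix with one column per chain, or a list of
#'   equal-length numeric vectors (>= 2 chains, each of length >= 2).
#' @return The scalar statistic.
#' @export
gelman_rubin <- function(series) {
  if (is.list(series)) series <- do.call(cbind, series)
  series <- as.matrix(series)
  m <- ncol(series); n <- nrow(series)
  if (m < 2L) stop("Gelman-Rubin needs >= 2 chains", call. = FALSE)
  if (n < 2L) stop("chains must have length >= 2", call. = FALSE)
  W <- mean(apply(series, 2, stats::var))
  B <- n * stats::var(colMeans(series))
  if (W == 0) {
    if (B == 0) return(1)
    return(Inf)
  }
  max(1, sqrt(((n - 1) / n * W + B / n) / W))
}

#' Summarize stock-group posterior proportions
#'
#' Group proportions per draw are deterministic sums of the member
#' populations' `theta`. Over the pooled post-burn-in draws the mean,
#' median, and equal-tailed 95% credibility interval (2.5/97.5 empirical
#' quantiles) are reported per group, with a per-group Gelman-Rubin
#' statistic across chains.
#'
#' @param draws A `gsi_posterior` from [run_chains()].
#' @param group_map Optional named map `population -> group`; defaults to
#'   the baseline's map carried in `draws`.
#' @return A `gsi_mixture_summary` data frame: `group, mean, median, q2.5,
#'   q97.5, gelman_rubin, converged`.
#' @export
summarize_groups <- function(draws, group_map = NULL) {
  stopifnot(inherits(draws, "gsi_posterior"))
  if (!is.null(group_map)) {
    miss <- setdiff(draws$populations, names(group_map))
    if (length(miss)) stop("group_map missing population(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    draws$group_map <- group_map
    draws$group_levels <- unique(unname(group_map[draws$populations]))
  }
  gs <- group_series(draws)
  pooled <- do.call(rbind, gs)
  n_chain <- length(gs)
  out <- data.frame(group = draws$group_levels,
                    mean = colMeans(pooled),
                    median = apply(pooled, 2, stats::median),
                    q2.5 = apply(pooled, 2, stats::quantile, probs = 0.025),
                    q97.5 = apply(pooled, 2, stats::quantile, probs = 0.975),
                    row.names = NULL)
  out$gelman_rubin <- if (n_chain >= 2L) {
    vapply(seq_along(draws$group_levels), function(g) {
      gelman_rubin(lapply(gs, function(s) s[, g]))
    }, numeric(1))
  } else NA_real_
  out$converged <- if (n_chain >= 2L) {
    out$gelman_rubin < draws$config$gr_threshold
  } else NA
  structure(out, class = c("gsi_mixture_summary", "data.frame"))
}
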