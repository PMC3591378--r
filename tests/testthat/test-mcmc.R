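test_that("spiked starting proportions follow the three-populations-at-0.3 rule", {
  set.seed(1)
  th <- initial_theta(13)
  expect_equal(sum(th), 1)
  expect_equal(sum(th == 0.3), 3L)
  expect_equal(sum(abs(th - 0.01) < 1e-12), 10L)
  th4 <- initial_theta(4)
  expect_equal(sort(th4), c(0.1, 0.3, 0.3, 0.3))
  expect_warning(th3 <- initial_theta(3), "K >= 4")
  expect_equal(th3, rep(1 / 3, 3))
  # each population lands in the high triple about 3/13 of the time
  set.seed(99)
  hits <- rowSums(replicate(1000, initial_theta(13) == 0.3))
  expect_true(all(abs(hits / 1000 - 3 / 13) < 4 * sqrt((3 / 13) * (10 / 13) / 1000)))
})

test_that("chain bookkeeping: retention, pooling, and draw normalization", {
  expect_error(chain_config(iterations = 100, thin = 7), "integer")
  cfg <- chain_config(n_chains = 2, iterations = 700, thin = 7, burn_in = 50,
                      seed = 5, update_allele_freqs = FALSE)
  d <- run_chains(tiny_baseline(), tiny_mixture(), config = cfg)
  expect_length(d$theta, 2L)
  expect_equal(nrow(d$theta[[1]]), 100L)  # iterations / thin retained
  expect_true(all(abs(rowSums(d$theta[[1]]) - 1) < 1e-9))
  expect_true(all(abs(rowSums(d$z_probs) - 1) < 1e-9))
  # pooled posterior mean is the average of per-chain post-burn-in means
  gs <- summarize_groups(d)
  per_chain <- sapply(d$theta, function(th) colMeans(th[51:100, ]))
  expect_equal(unname(gs$mean), unname(rowMeans(per_chain)), tolerance = 1e-12)
})

test_that("identical inputs and seed give bit-identical draws", {
  cfg <- chain_config(n_chains = 2, iterations = 500, thin = 5, burn_in = 10,
                      seed = 77)
  b <- tiny_baseline(); m <- tiny_mixture()
  d1 <- run_chains(b, m, config = cfg)
  d2 <- run_chains(b, m, config = cfg)
  expect_identical(d1$theta, d2$theta)
  expect_identical(d1$z_probs, d2$z_probs)
  # chains differ from one another (distinct randomized starts/seeds)
  expect_false(identical(d1$theta[[1]], d1$theta[[2]]))
})

test_that("a fish impossible everywhere but one population is always assigned there", {
  cfg <- chain_config(n_chains = 1, iterations = 200, thin = 1, burn_in = 0,
                      seed = 3, update_allele_freqs = FALSE)
  d <- run_chains(tiny_baseline(), tiny_mixture(c("A/A", "A/A")),
                  config = cfg, freqs = tiny_freqs(pA = c(1, 0)))
  expect_equal(unname(d$z_probs[, "p1"]), c(1, 1))
})

test_that("with all genotypes missing the posterior equals the Dirichlet prior", {
  loci <- list(locus_def("snp1", "diploid_nuclear", c("A", "C")))
  mix <- genotype_table(data.frame(individual_id = paste0("m", 1:3),
                                   snp1 = NA_character_), loci)
  cfg <- chain_config(n_chains = 2, iterations = 60000, thin = 2,
                      burn_in = 1000, seed = 12, update_allele_freqs = FALSE)
  expect_warning(d <- run_chains(tiny_baseline(), mix, config = cfg),
                 "prior alone")
  th <- do.call(rbind, lapply(d$theta, function(x) x[-(1:1000), ]))
  # Dirichlet(1/2, 1/2): mean 1/2, variance ab/((a+b)^2 (a+b+1)) = 1/8
  expect_equal(mean(th[, 1]), 0.5, tolerance = 0.01)
  expect_equal(var(th[, 1]), 1 / 8, tolerance = 0.01)
})

test_that("Gibbs posterior matches exhaustive enumeration on a tiny instance", {
  # 2 populations, 1 biallelic locus, 4 fish, fixed allele frequencies
  pA <- c(0.9, 0.2)
  calls <- c("A/A", "A/C", "C/C", "A/C")
  L <- t(vapply(calls, function(g) c(hwe_lik(g, pA[1]), hwe_lik(g, pA[2])),
                numeric(2)))
  oracle <- enumerate_posterior(L, alpha = c(0.5, 0.5))
  cfg <- chain_config(n_chains = 1, iterations = 60000, thin = 1,
                      burn_in = 5000, seed = 8, update_allele_freqs = FALSE)
  d <- run_chains(tiny_baseline(), tiny_mixture(calls), config = cfg,
                  freqs = tiny_freqs(pA))
  gibbs_theta <- colMeans(d$theta[[1]][-(1:5000), ])
  expect_equal(unname(gibbs_theta), oracle$theta, tolerance = 0.01)
  expect_equal(unname(d$z_probs), unname(oracle$z_probs), tolerance = 0.02)
})

test_that("Gelman-Rubin diagnostic behaves at its limits", {
  x <- rnorm(100)
  expect_equal(gelman_rubin(cbind(x, x)), 1)          # identical chains
  set.seed(4)
  same <- matrix(rnorm(20000), ncol = 2)              # same distribution
  expect_lt(gelman_rubin(same), 1.05)
  apart <- cbind(rnorm(200, 0.2, 1e-4), rnorm(200, 0.8, 1e-4))
  expect_gt(gelman_rubin(apart), 10)                  # non-overlapping
  expect_equal(gelman_rubin(cbind(rep(1, 5), rep(1, 5))), 1)  # W = B = 0
  expect_error(gelman_rubin(matrix(1:5, ncol = 1)), ">= 2 chains")
})

test_that("group summaries use empirical quantiles and deterministic group sums", {
  cfg <- chain_config(n_chains = 2, iterations = 1000, thin = 1,
                      burn_in = 500, seed = 21, update_allele_freqs = FALSE)
  d <- run_chains(tiny_baseline(), tiny_mixture(), config = cfg)
  s <- summarize_groups(d)
  expect_true(all(s$q2.5 <= s$median & s$median <= s$q97.5))
  expect_equal(sum(s$mean), 1, tolerance = 1e-12)
  # sort-and-index oracle for the quantiles on the pooled series
  pooled <- do.call(rbind, lapply(d$theta, function(x) x[-(1:500), 1]))
  expect_equal(s$q2.5[1], unname(quantile(as.numeric(pooled), 0.025)),
               tolerance = 1e-12)
  # degenerate draws: all identical
  d0 <- d
  d0$theta <- lapply(d0$theta, function(x) {
    x[] <- rep(c(0.4, 0.6), each = nrow(x)); x
  })
  s0 <- summarize_groups(d0)
  expect_equal(s0$mean, s0$median)
  expect_equal(s0$q97.5 - s0$q2.5, c(0, 0))
  expect_error(summarize_groups(d, group_map = c(p1 = "g1")), "missing")
  # single chain: diagnostic not computable
  cfg1 <- chain_config(n_chains = 1, iterations = 400, thin = 2, burn_in = 50,
                       seed = 9, update_allele_freqs = FALSE)
  s1 <- summarize_groups(run_chains(tiny_baseline(), tiny_mixture(),
                                    config = cfg1))
  expect_true(all(is.na(s1$gelman_rubin)))
})

test_that("full-model and fixed-frequency variants agree on an informative mixture", {
  base <- simulate_baseline(small_design(seed = 31, differentiation = 0.3))
  mix <- simulate_mixture(base$true_freqs, base$group_map, c(0.5, 0.5),
                          n = 40, missing_rate = 0, seed = 32)
  cfg_on <- chain_config(n_chains = 2, iterations = 4000, thin = 2,
                         burn_in = 500, seed = 33)
  cfg_off <- cfg_on; cfg_off$update_allele_freqs <- FALSE
  s_on <- summarize_groups(run_chains(base$baseline, mix$records,
                                      config = cfg_on))
  s_off <- summarize_groups(run_chains(base$baseline, mix$records,
                                       config = cfg_off))
  expect_equal(s_on$mean, s_off$mean, tolerance = 0.05)
})
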