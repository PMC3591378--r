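# Build an individual-posterior table directly from a probability matrix.
fake_posteriors <- function(P, groups = paste0("g", seq_len(ncol(P)))) {
  colnames(P) <- groups
  structure(data.frame(individual_id = paste0("f", seq_len(nrow(P))), P,
                       check.names = FALSE),
            groups = groups,
            class = c("gsi_indiv_posterior", "data.frame"))
}

test_that("threshold assignment is inclusive and bounded away from ambiguity", {
  P <- rbind(c(1.00, 0.00, 0.00),
             c(0.79, 0.20, 0.01),
             c(0.80, 0.15, 0.05))
  post <- fake_posteriors(P)
  a <- assign_individuals(post, 0.8)
  expect_identical(a$assigned_group, c("g1", "NOT_ASSIGNED", "g1"))
  expect_equal(a$top_prob, c(1.0, 0.79, 0.80))
  expect_error(assign_individuals(post, 0.4), "threshold")
  expect_error(assign_individuals(post, 1.2), "threshold")
})

test_that("assignment counts are non-increasing in the threshold", {
  set.seed(15)
  raw <- matrix(rexp(300 * 3), ncol = 3)
  post <- fake_posteriors(raw / rowSums(raw))
  grid <- seq(0.5, 0.95, by = 0.05)
  n_assigned <- vapply(grid, function(th) {
    sum(assign_individuals(post, th)$assigned_group != "NOT_ASSIGNED")
  }, numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("sample proportions include the unassigned class and match hand tallies", {
  P <- rbind(matrix(rep(c(0.9, 0.05, 0.05), 4), ncol = 3, byrow = TRUE),
             matrix(rep(c(0.1, 0.85, 0.05), 3), ncol = 3, byrow = TRUE),
             matrix(rep(c(0.4, 0.4, 0.2), 3), ncol = 3, byrow = TRUE))
  a <- assign_individuals(fake_posteriors(P), 0.8)
  p <- summarize_assignments(a)
  expect_equal(unname(p), c(0.4, 0.3, 0, 0.3))  # 4, 3, 0 assigned; 3 not
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # all below threshold
  a2 <- assign_individuals(fake_posteriors(matrix(1 / 3, 5, 3)), 0.8)
  expect_equal(unname(summarize_assignments(a2)), c(0, 0, 0, 1))
})

test_that("holdout removal conserves baseline allele counts", {
  base <- simulate_baseline(small_design(seed = 41))
  ind <- base$baseline$individuals
  hold <- ind$individual_id[c(3, 17, 55, 120, 160)]
  keep_tbl <- ind[!ind$individual_id %in% hold, ]
  held_tbl <- ind[ind$individual_id %in% hold, ]
  attr(keep_tbl, "loci") <- table_loci(ind)
  attr(held_tbl, "loci") <- table_loci(ind)
  class(keep_tbl) <- class(held_tbl) <- c("gsi_genotypes", "data.frame")
  b_keep <- baseline_from_individuals(keep_tbl, base$group_map)
  b_held <- baseline_from_individuals(held_tbl, base$group_map)
  merged <- merge(b_keep$counts, b_held$counts,
                  by = c("population", "stock_group", "locus", "allele"))
  merged$total <- merged$count.x + merged$count.y
  orig <- merge(merged, base$baseline$counts,
                by = c("population", "stock_group", "locus", "allele"))
  expect_equal(orig$total, orig$count)
})

test_that("calibration error rates match a confusion-matrix tally on one replicate", {
  base <- simulate_baseline(small_design(seed = 51, differentiation = 0.15))
  cfg <- chain_config(n_chains = 1, iterations = 1000, thin = 1,
                      burn_in = 200, seed = 52)
  rep1 <- holdout_calibration(base$baseline, mixture_size = 40,
                              group_proportions = c(0.5, 0.5),
                              n_replicates = 1, thresholds = c(0.6, 0.8),
                              config = cfg, seed = 53)
  d <- rep1$detail
  # error rate and assigned fraction recompute from the raw counts
  expect_equal(d$error_rate[!is.na(d$error_rate)],
               (d$n_wrong / d$n_assigned)[!is.na(d$error_rate)])
  expect_equal(d$assigned_fraction, d$n_assigned / 40)
  # relaxing the threshold never assigns fewer fish to a group
  by_group <- split(d, d$group)
  for (g in by_group) {
    expect_gte(g$n_assigned[g$threshold == 0.6],
               g$n_assigned[g$threshold == 0.8])
  }
})

test_that("perfectly differentiated baselines assign everyone without error", {
  # two populations fixed for alternate alleles at every locus
  loci <- lapply(1:8, function(j) {
    locus_def(sprintf("L%d", j), "diploid_nuclear", c("A", "C"))
  })
  mk <- function(ids, pop, call) {
    df <- data.frame(individual_id = ids, population = pop)
    for (j in 1:8) df[[sprintf("L%d", j)]] <- call
    df
  }
  ind <- genotype_table(rbind(mk(sprintf("a%02d", 1:30), "p1", "A/A"),
                              mk(sprintf("b%02d", 1:30), "p2", "C/C")), loci)
  base <- baseline_from_individuals(ind, c(p1 = "gA", p2 = "gB"))
  cfg <- chain_config(n_chains = 1, iterations = 600, thin = 1,
                      burn_in = 100, seed = 61)
  rep1 <- holdout_calibration(base, mixture_size = 20,
                              group_proportions = c(0.5, 0.5),
                              n_replicates = 2,
                              thresholds = seq(0.5, 0.9, 0.1),
                              config = cfg, seed = 62)
  s <- rep1$summary
  expect_true(all(s$mean_error[!is.na(s$mean_error)] == 0))
  agg <- tapply(s$mean_assigned_fraction, s$threshold, sum)
  expect_true(all(agg == 1))  # whole mixture assigned at every threshold
})

test_that("holdout draws fail loudly when a population would be exhausted", {
  base <- simulate_baseline(small_design(seed = 71))
  expect_error(
    holdout_calibration(base$baseline, mixture_size = 150,
                        group_proportions = c(1, 0), n_replicates = 1,
                        config = short_chains(1), seed = 72),
    "larger baseline")
})

test_that("threshold choice scans the grid against the error ceiling", {
  mk_report <- function(err_by_th) {
    summary <- do.call(rbind, lapply(names(err_by_th), function(th) {
      data.frame(threshold = as.numeric(th), group = c("gA", "gB"),
                 mean_error = err_by_th[[th]], sd_error = 0.01,
                 mean_assigned_fraction = 0.5, n_defined = 10)
    }))
    structure(list(summary = summary,
                   thresholds = as.numeric(names(err_by_th)),
                   groups = c("gA", "gB"), detail = NULL, config = NULL),
              class = "gsi_calibration_report")
  }
  rep1 <- mk_report(list(`0.5` = c(0.25, 0.10), `0.8` = c(0.11, 0.04),
                         `0.9` = c(0.03, 0.03)))
  expect_equal(choose_threshold(rep1, 0.15), 0.8)
  # exhaustive scan oracle
  scan <- Filter(function(th) {
    all(rep1$summary$mean_error[rep1$summary$threshold == th] < 0.15)
  }, rep1$thresholds)
  expect_equal(choose_threshold(rep1, 0.15), min(unlist(scan)))
  # all zero errors: lowest threshold wins
  rep0 <- mk_report(list(`0.5` = c(0, 0), `0.9` = c(0, 0)))
  expect_equal(choose_threshold(rep0), 0.5)
  # nothing qualifies: highest threshold, with a warning
  repbad <- mk_report(list(`0.5` = c(0.5, 0.4), `0.9` = c(0.4, 0.3)))
  expect_warning(th <- choose_threshold(repbad, 0.15), "ceiling")
  expect_equal(th, 0.9)
})
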