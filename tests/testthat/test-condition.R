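test_that("noiseless data recover generating coefficients exactly", {
  # both groups on one line
  d1 <- simulate_condition(condition_design(
    groups = c("a", "b"), intercept = c(-5, -5), slope = c(3.1, 3.1),
    resid_sd = c(0, 0), length_mean = c(65, 65), length_sd = c(6, 6),
    n = c(40, 40), seed = 2))
  f <- fit_condition_model(d1, "M_shared")
  expect_equal(unname(f$coefficients), c(-5, 3.1), tolerance = 1e-10)
  expect_lt(f$rss, 1e-20)
  # two parallel lines: intercept model recovers both intercepts
  d2 <- simulate_condition(condition_design(
    groups = c("a", "b"), intercept = c(-5, -5.2), slope = c(3.1, 3.1),
    resid_sd = c(0, 0), length_mean = c(65, 65), length_sd = c(6, 6),
    n = c(40, 40), seed = 3))
  f2 <- fit_condition_model(d2, "M_intercepts")
  cf <- f2$coefficients
  expect_equal(unname(cf[["(Intercept)"]]), -5, tolerance = 1e-10)
  expect_equal(unname(cf[["(Intercept)"]] + cf[["groupb"]]), -5.2,
               tolerance = 1e-10)
  expect_equal(unname(cf[["x"]]), 3.1, tolerance = 1e-10)
})

test_that("least-squares coefficients match a normal-equations solve", {
  set.seed(9)
  len <- c(rnorm(6, 65, 5), rnorm(6, 70, 5))
  grp <- rep(c("a", "b"), each = 6)
  mass <- 10^(-5 + 3 * log10(len) + rnorm(12, 0, 0.05))
  d <- condition_data(grp, len, mass)
  f <- fit_condition_model(d, "M_full")
  X <- cbind(1, grp == "b", log10(len) * (grp == "a"),
             log10(len) * (grp == "b"))
  beta <- normal_equations(X, log10(mass))
  expect_equal(unname(f$coefficients), unname(beta), tolerance = 1e-8)
  expect_equal(f$k, 5L)
  expect_equal(f$n, 12L)
})

test_that("AICc matches the small-sample formula and its large-n limit", {
  # independently scripted evaluation at k=3, n=10, rss=1
  expect_equal(aicc(1, 10, 3), 10 * log(1 / 10) + 6 + 24 / 6)
  # correction vanishes as n grows
  n <- 1e6
  aic <- n * log(2.5 / n) + 2 * 4
  expect_lt(abs(aicc(2.5, n, 4) - aic), 1e-4)
  # symmetry: equal rss and k give equal AICc
  expect_identical(aicc(3.2, 50, 4), aicc(3.2, 50, 4))
  expect_error(aicc(1, 4, 3), "undefined")
})

test_that("Akaike weights normalize, shift-invariantly", {
  w <- akaike_weights(c(100, 102, 104))
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  w2 <- akaike_weights(c(100, 102, 104) + 57.3)
  expect_equal(w$weight, w2$weight, tolerance = 1e-12)
  expect_equal(w$delta, c(0, 2, 4))
  expect_equal(akaike_weights(5)$weight, 1)
})

test_that("residual sums of squares nest across the four models", {
  d <- simulate_condition(condition_design(seed = 13))
  cmp <- compare_condition(d)
  rss <- setNames(cmp$rss, cmp$model)
  expect_lte(rss[["M_full"]], rss[["M_intercepts"]])
  expect_lte(rss[["M_full"]], rss[["M_slopes"]])
  expect_lte(rss[["M_intercepts"]], rss[["M_shared"]])
  expect_lte(rss[["M_slopes"]], rss[["M_shared"]])
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-12)
  expect_equal(min(cmp$delta_aicc), 0)
  expect_equal(sum(cmp$delta_aicc == 0), 1L)
})

test_that("the group factor only ever helps: relabelings nest the shared fit", {
  d <- simulate_condition(condition_design(seed = 17))
  shared <- fit_condition_model(d, "M_shared")
  # merging both groups into one label leaves nothing to fit group terms on
  expect_error(fit_condition_model(
    condition_data(rep("one", nrow(d)), d$length_mm, d$mass_g),
    "M_intercepts"), "two groups")
  # under an arbitrary 2-level relabeling the grouped models still nest the
  # shared fit on the same rows, and with balanced duplicate labels their
  # group contrasts shrink toward zero
  half <- rep(c("h1", "h2"), length.out = nrow(d))
  d3 <- condition_data(half, d$length_mm, d$mass_g)
  for (m in c("M_intercepts", "M_slopes", "M_full")) {
    expect_lte(fit_condition_model(d3, m)$rss, shared$rss + 1e-12)
  }
})

test_that("the generating model wins the comparison on well-separated data", {
  # strong group differences in both intercept and slope, large n
  d <- simulate_condition(condition_design(
    groups = c("a", "b"), intercept = c(-5.0, -5.6), slope = c(3.0, 3.35),
    resid_sd = c(0.04, 0.04), length_mean = c(66, 66), length_sd = c(8, 8),
    n = c(250, 250), seed = 23))
  cmp <- compare_condition(d)
  expect_equal(cmp$model[1], "M_full")
  expect_gt(cmp$weight[1], 0.9)
  # data from the shared model: the parsimonious model attains the lowest
  # AICc in expectation over seeds
  mean_aicc <- rowMeans(vapply(1:20, function(s) {
    ds <- simulate_condition(condition_design(
      groups = c("a", "b"), intercept = c(-5, -5), slope = c(3.1, 3.1),
      resid_sd = c(0.05, 0.05), length_mean = c(66, 66), length_sd = c(7, 7),
      n = c(120, 120), seed = 100 + s))
    cs <- compare_condition(ds)
    setNames(cs$aicc, cs$model)[c("M_shared", "M_intercepts", "M_slopes",
                                  "M_full")]
  }, numeric(4)))
  expect_equal(names(which.min(mean_aicc)), "M_shared")
})

test_that("Bartlett's test gates the choice between ANOVA and Kruskal-Wallis", {
  # equal variances: homoscedastic branch taken except for the expected
  # ~alpha Bartlett false positives; ANOVA p roughly uniform under the null
  res <- lapply(1:50, function(s) {
    set.seed(400 + s)
    d <- condition_data(rep(c("a", "b"), each = 200),
                        rnorm(400, 65, 6), rep(3, 400))
    compare_lengths(d)
  })
  branch <- vapply(res, `[[`, character(1), "chosen_test")
  expect_gte(mean(branch == "ANOVA"), 0.85)
  ps <- vapply(res[branch == "ANOVA"], `[[`, numeric(1), "p_value")
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  # variances 1 vs 25: heteroscedastic branch essentially always
  branch <- vapply(1:50, function(s) {
    set.seed(500 + s)
    d <- condition_data(rep(c("a", "b"), each = 200),
                        c(rnorm(200, 65, 1), rnorm(200, 65, 5)), rep(3, 400))
    compare_lengths(d)$chosen_test
  }, character(1))
  expect_gte(mean(branch == "Kruskal-Wallis"), 0.95)
})

test_that("identical groups give a near-zero statistic and Tukey runs for 3 groups", {
  set.seed(77)
  len <- rnorm(60, 65, 5)
  d <- condition_data(rep(c("a", "b"), 30), rep(len[1:30], each = 2),
                      rep(3, 60))
  res <- compare_lengths(d)
  expect_lt(res$statistic, 1e-20)
  expect_gt(res$p_value, 0.999)
  # three-group comparison under ANOVA reports Tukey pairs
  d3 <- condition_data(rep(c("a", "b", "unassigned"), each = 50),
                       rnorm(150, 65, 6), rep(3, 150))
  res3 <- compare_lengths(d3)
  if (res3$chosen_test == "ANOVA") {
    expect_equal(nrow(res3$tukey), 3L)
    expect_equal(res3$df_between, 2)
  }
  # zero-variance group falls through to Kruskal-Wallis with a note
  dz <- condition_data(rep(c("a", "b"), each = 10),
                       c(rep(65, 10), rnorm(10, 65, 3)), rep(3, 20))
  resz <- compare_lengths(dz)
  expect_identical(resz$chosen_test, "Kruskal-Wallis")
  expect_match(resz$note, "zero")
})
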