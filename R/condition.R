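CONDITION_MODELS <- c("M_shared", "M_intercepts", "M_slopes", "M_full")

#' Assemble a body-condition dataset
#'
#' @param group Group label per fish (e.g. stock-of-origin by capture
#'   location); two groups for model fitting, optionally a third
#'   "unassigned" class for length comparisons.
#' @param length_mm Fork length in mm, strictly positive.
#' @param mass_g Wet mass in g, strictly positive.
#' @return A `gsi_condition` data frame.
#' @export
condition_data <- function(group, length_mm, mass_g) {
  stopifnot(length(group) == length(length_mm),
            length(group) == length(mass_g))
  if (any(length_mm <= 0) || any(mass_g <= 0)) {
    stop("lengths and masses must be strictly positive", call. = FALSE)
  }
  structure(data.frame(group = as.character(group), length_mm = length_mm,
                       mass_g = mass_g),
            class = c("gsi_condition", "data.frame"))
}

transform_fun <- function(transform = c("log10", "ln", "none")) {
  switch(match.arg(transform), log10 = log10, ln = log, none = identity)
}

#' Fit one grouped length-mass regression
#'
#' The four candidate models regress transformed mass on transformed length
#' (log10 by default, the standard allometric condition-factor scale) with
#' different intercept/slope sharing between the two groups:
#' `M_shared` (one intercept B0, one slope B1), `M_intercepts` (group
#' intercepts B01/B02, shared slope B1), `M_slopes` (shared intercept B0,
#' group slopes B11/B12), and `M_full` (group intercepts and slopes).
#' All are ordinary least squares fits on identical data. The parameter
#' count `k` includes the residual variance by default
#' (k = 3, 4, 4, 5 respectively).
#'
#' @param data A [condition_data()] with exactly two groups.
#' @param model_id One of `"M_shared", "M_intercepts", "M_slopes",
#'   "M_full"`.
#' @param transform `"log10"` (default), `"ln"`, or `"none"`.
#' @param count_sigma Count the residual variance in `k` (default `TRUE`).
#' @return A `gsi_condition_fit` list: `model_id, coefficients, n, k, rss,
#'   aicc, transform`.
#' @export
fit_condition_model <- function(data, model_id = CONDITION_MODELS,
                                transform = "log10", count_sigma = TRUE) {
  model_id <- match.arg(model_id)
  stopifnot(inherits(data, "gsi_condition"))
  groups <- unique(data$group)
  if (length(groups) != 2L) {
    stop("condition models compare exactly two groups", call. = FALSE)
  }
  n_per <- table(data$group)
  if (any(n_per < 3L)) {
    stop("each group needs at least 3 fish", call. = FALSE)
  }
  f <- transform_fun(transform)
  d <- data.frame(y = f(data$mass_g), x = f(data$length_mm),
                  group = factor(data$group, levels = groups))
  if (model_id %in% c("M_slopes", "M_full")) {
    v <- tapply(d$x, d$group, stats::var)
    if (any(v == 0)) {
      stop("a group has zero length variance; slope-varying models are not ",
           "identifiable", call. = FALSE)
    }
  }
  form <- switch(model_id,
                 M_shared     = y ~ x,
                 M_intercepts = y ~ group + x,
                 M_slopes     = y ~ x:group,
                 M_full       = y ~ group + x:group)
  fit <- stats::lm(form, data = d)
  n <- nrow(d)
  k <- length(stats::coef(fit)) + if (count_sigma) 1L else 0L
  rss <- sum(stats::residuals(fit)^2)
  structure(list(model_id = model_id, coefficients = stats::coef(fit),
                 n = n, k = k, rss = rss, aicc = aicc(rss, n, k),
                 transform = transform, lm = fit),
            class = "gsi_condition_fit")
}

#' @export
print.gsi_condition_fit <- function(x, ...) {
  cat(sprintf("<gsi_condition_fit> %s: n=%d k=%d rss=%.5g AICc=%.3f\n",
              x$model_id, x$n, x$k, x$rss, x$aicc))
  invisible(x)
}

#' Small-sample-corrected Akaike information criterion
#'
#' For a least-squares fit: `AICc = n*ln(rss/n) + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations; must exceed `k + 1`.
#' @param k Parameter count (including the residual variance).
#' @return The AICc value.
#' @export
aicc <- function(rss, n, k) {
  if (n <= k + 1) stop("AICc undefined for n <= k + 1", call. = FALSE)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike differences and weights
#'
#' `delta_i = AICc_i - min(AICc)`;
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)`. Each `w_i` estimates
#' the probability that model `i` is the best model in the candidate set.
#'
#' @param aicc_values Finite AICc (or, equivalently, delta-AICc) values.
#' @return List with `delta` and `weight`, both in input order; weights sum
#'   to 1.
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(length(aicc_values) >= 1L, all(is.finite(aicc_values)))
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  list(delta = delta, weight = w / sum(w))
}

#' Round half away from zero
#'
#' Presentation-grade rounding (0.005 -> 0.01 at 2 digits), unlike base
#' [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Fit and rank the four condition models
#'
#' Fits all four intercept/slope-sharing structures on identical data,
#' computes AICc, delta-AICc, and Akaike weights jointly, and ranks by
#' AICc (best first).
#'
#' @inheritParams fit_condition_model
#' @return A `gsi_condition_comparison` data frame (`model, n, k, rss,
#'   aicc, delta_aicc, weight`), ranked by AICc, with the individual fits
#'   in the `fits` attribute.
#' @export
compare_condition <- function(data, transform = "log10", count_sigma = TRUE) {
  fits <- lapply(CONDITION_MODELS, function(m) {
    fit_condition_model(data, m, transform = transform,
                        count_sigma = count_sigma)
  })
  names(fits) <- CONDITION_MODELS
  av <- vapply(fits, `[[`, numeric(1), "aicc")
  aw <- akaike_weights(av)
  out <- data.frame(model = CONDITION_MODELS,
                    n = vapply(fits, `[[`, numeric(1), "n"),
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    rss = vapply(fits, `[[`, numeric(1), "rss"),
                    aicc = av, delta_aicc = aw$delta, weight = aw$weight,
                    row.names = NULL)
  out <- out[order(out$aicc), ]
  rownames(out) <- NULL
  structure(out, fits = fits,
            class = c("gsi_condition_comparison", "data.frame"))
}

#' Compare group length distributions
#'
#' Homogeneity of variances is tested first with Bartlett's test; if the
#' variances are homoscedastic (p >= alpha) a one-way ANOVA is used, with
#' Tukey honest-significant-difference pairwise comparisons when more than
#' two groups are present; if heteroscedastic, the non-parametric
#' Kruskal-Wallis rank test is used instead. A group with zero length
#' variance leaves Bartlett's statistic undefined and falls through to
#' Kruskal-Wallis with a note.
#'
#' @param data A [condition_data()] with 2-3 groups, >= 2 fish per group.
#' @param alpha Significance level gating the Bartlett test (default 0.05).
#' @return A `gsi_length_comparison` list: `bartlett_stat, bartlett_p,
#'   chosen_test, statistic, df_between, df_residual, p_value, tukey`
#'   (ANOVA with > 2 groups only), `note`.
#' @export
compare_lengths <- function(data, alpha = 0.05) {
  stopifnot(inherits(data, "gsi_condition"))
  data$group <- factor(data$group)
  n_groups <- nlevels(data$group)
  if (n_groups < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(data$group) < 2L)) {
    stop("each group needs at least 2 fish", call. = FALSE)
  }
  note <- NULL
  v <- tapply(data$length_mm, data$group, stats::var)
  if (any(v == 0)) {
    bart_stat <- NA_real_; bart_p <- NA_real_
    hetero <- TRUE
    note <- "zero within-group variance: Bartlett undefined, using Kruskal-Wallis"
  } else {
    bart <- stats::bartlett.test(length_mm ~ group, data = data)
    bart_stat <- unname(bart$statistic)
    bart_p <- bart$p.value
    hetero <- bart_p < alpha
  }
  if (hetero) {
    kw <- stats::kruskal.test(length_mm ~ group, data = data)
    out <- list(bartlett_stat = bart_stat, bartlett_p = bart_p,
                chosen_test = "Kruskal-Wallis",
                statistic = unname(kw$statistic),
                df_between = unname(kw$parameter), df_residual = NA_real_,
                p_value = kw$p.value, tukey = NULL, note = note)
  } else {
    av <- stats::aov(length_mm ~ group, data = data)
    tab <- summary(av)[[1]]
    tukey <- if (n_groups > 2L) {
      as.data.frame(stats::TukeyHSD(av)$group)
    } else NULL
    out <- list(bartlett_stat = bart_stat, bartlett_p = bart_p,
                chosen_test = "ANOVA",
                statistic = tab[["F value"]][1],
                df_between = tab[["Df"]][1], df_residual = tab[["Df"]][2],
                p_value = tab[["Pr(>F)"]][1], tukey = tukey, note = note)
  }
  structure(out, class = "gsi_length_comparison")
}

#' @export
print.gsi_length_comparison <- function(x, ...) {
  cat(sprintf(
    "<gsi_length_comparison> Bartlett p=%.4g -> %s: stat=%.4g, p=%.4g\n",
    x$bartlett_p, x$chosen_test, x$statistic, x$p_value))
  invisible(x)
}
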