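NOT_ASSIGNED <- "NOT_ASSIGNED"

#' Per-individual stock-group posterior probabilities
#'
#' Sums each fish's population-level origin probabilities over the member
#' populations of each stock group.
#'
#' @param draws A `gsi_posterior` from [run_chains()].
#' @return A `gsi_indiv_posterior` data frame: `individual_id` plus one
#'   probability column per group (rows sum to 1).
#' @export
individual_posteriors <- function(draws) {
  stopifnot(inherits(draws, "gsi_posterior"))
  G <- outer(unname(draws$group_map[draws$populations]), draws$group_levels,
             `==`) * 1
  probs <- draws$z_probs %*% G
  colnames(probs) <- draws$group_levels
  out <- data.frame(individual_id = draws$individual_id, probs,
                    check.names = FALSE)
  structure(out, groups = draws$group_levels,
            class = c("gsi_indiv_posterior", "data.frame"))
}

#' Threshold assignment of individuals to stock groups
#'
#' Each individual is assigned to its highest-probability group when that
#' probability is at least `threshold` (inclusive, so exactly 0.80 assigns
#' at the 80% threshold), otherwise it is `NOT_ASSIGNED`. Thresholds below
#' 0.5 are rejected (more than one group could qualify); at exactly 0.5 the
#' assignment is still unique because only the top group is considered.
#'
#' @param posteriors A [individual_posteriors()] result.
#' @param threshold Probability cutoff in \[0.5, 1\].
#' @return A `gsi_assignments` data frame: `individual_id, assigned_group,
#'   top_prob, threshold`.
#' @export
assign_individuals <- function(posteriors, threshold = 0.8) {
  stopifnot(inherits(posteriors, "gsi_indiv_posterior"))
  if (threshold < 0.5 || threshold > 1) {
    stop("threshold must be in [0.5, 1]", call. = FALSE)
  }
  groups <- attr(posteriors, "groups")
  probs <- as.matrix(as.data.frame(posteriors)[groups])
  top <- max.col(probs, ties.method = "first")
  top_prob <- probs[cbind(seq_len(nrow(probs)), top)]
  assigned <- ifelse(top_prob >= threshold, groups[top], NOT_ASSIGNED)
  out <- data.frame(individual_id = posteriors$individual_id,
                    assigned_group = assigned, top_prob = top_prob,
                    threshold = threshold)
  structure(out, groups = groups,
            class = c("gsi_assignments", "data.frame"))
}

#' Proportions of the sample assigned to each group
#'
#' Proportions are taken over all individuals, assigned or not, so the
#' `NOT_ASSIGNED` category is included and the proportions sum to 1.
#'
#' @param results A [assign_individuals()] result.
#' @return Named numeric vector over the stock groups plus `NOT_ASSIGNED`.
#' @export
summarize_assignments <- function(results) {
  stopifnot(inherits(results, "gsi_assignments"), nrow(results) > 0)
  levels <- c(attr(results, "groups"), NOT_ASSIGNED)
  tab <- table(factor(results$assigned_group, levels = levels))
  as.vector(tab) / nrow(results) -> p
  stats::setNames(p, levels)
}

# Integer apportionment of `total` by `weights` (largest-remainder rule).
largest_remainder <- function(weights, total) {
  if (total == 0L || sum(weights) == 0) return(rep(0L, length(weights)))
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0L) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Known-mixture holdout calibration of assignment error rates
#'
#' Repeats, `n_replicates` times: (1) draw `mixture_size` individuals from
#' the baseline populations so that group totals match `group_proportions`
#' (populations within a group are drawn in proportion to their baseline
#' sample sizes, largest-remainder rounding); (2) rebuild the baseline
#' counts without the held-out individuals; (3) run the full MCMC and
#' individual assignment on the held-out test mixture; (4) at each
#' threshold and group, score the error rate (individuals assigned to the
#' group whose true group differs, over individuals assigned to the group)
#' and the assigned fraction (individuals assigned to the group over
#' `mixture_size`). Means and SDs are taken across replicates; replicates
#' where no one was assigned to a group leave that replicate's error rate
#' undefined and it is excluded from the mean (`n_defined` records how many
#' replicates contributed).
#'
#' @param baseline A [baseline_set()] carrying individual-level genotypes.
#' @param mixture_size Test-mixture size (the field-standard design uses
#'   200).
#' @param group_proportions Named or ordered proportions per stock group,
#'   summing to 1; groups at 0 contribute no fish but remain assignable.
#' @param n_replicates Number of holdout replicates (default 10).
#' @param thresholds Ascending grid of assignment thresholds
#'   (default `seq(0.5, 0.9, 0.1)`).
#' @param prior A [prior_spec()].
#' @param config A [chain_config()]; calibration replicates may use a
#'   reduced configuration, which is recorded in the report.
#' @param seed Integer seed for the holdout draws and the per-replicate
#'   chains.
#' @return A `gsi_calibration_report`: `summary` (per threshold x group:
#'   `mean_error, sd_error, mean_assigned_fraction, n_defined`), `detail`
#'   (per replicate), `thresholds`, and the `config` used.
#' @export
holdout_calibration <- function(baseline, mixture_size = 200L,
                                group_proportions, n_replicates = 10L,
                                thresholds = seq(0.5, 0.9, by = 0.1),
                                prior = prior_spec(),
                                config = chain_config(), seed = 1L) {
  stopifnot(inherits(baseline, "gsi_baseline"))
  if (is.null(baseline$individuals)) {
    stop("holdout calibration needs individual-level baseline genotypes",
         call. = FALSE)
  }
  groups <- baseline$group_levels
  if (!is.null(names(group_proportions))) {
    group_proportions <- group_proportions[groups]
  }
  stopifnot(length(group_proportions) == length(groups),
            abs(sum(group_proportions) - 1) < 1e-8)
  thresholds <- sort(thresholds)

  ind <- baseline$individuals
  pop_of <- ind$population
  group_of_pop <- baseline$group_map
  set.seed(seed)
  rep_seeds <- sample.int(2147483000L, n_replicates)

  detail <- list()
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    n_group <- largest_remainder(group_proportions, mixture_size)
    hold_idx <- integer(0)
    for (g in seq_along(groups)) {
      if (n_group[g] == 0L) next
      pops_g <- names(group_of_pop)[group_of_pop == groups[g]]
      sizes <- vapply(pops_g, function(p) sum(pop_of == p), integer(1))
      n_pop <- largest_remainder(sizes, n_group[g])
      short <- n_pop > sizes
      if (any(short)) {
        stop("holdout draw exhausts population(s) ",
             paste(pops_g[short], collapse = ", "),
             "; use a larger baseline or a smaller mixture", call. = FALSE)
      }
      for (j in seq_along(pops_g)) {
        if (n_pop[j] == 0L) next
        cand <- which(pop_of == pops_g[j])
        hold_idx <- c(hold_idx, sample(cand, n_pop[j]))
      }
    }
    held <- subset_genotypes(ind, hold_idx)
    rest <- subset_genotypes(ind, -hold_idx)
    base_r <- baseline_from_individuals(rest, baseline$group_map)
    true_group <- unname(group_of_pop[held$population])

    cfg <- config
    cfg$seed <- rep_seeds[r]
    draws <- run_chains(base_r, held, prior, cfg)
    post <- individual_posteriors(draws)

    for (th in thresholds) {
      asg <- assign_individuals(post, th)
      for (g in groups) {
        to_g <- asg$assigned_group == g
        n_asg <- sum(to_g)
        n_wrong <- sum(to_g & true_group != g)
        detail[[length(detail) + 1L]] <- data.frame(
          replicate = r, threshold = th, group = g,
          n_assigned = n_asg, n_wrong = n_wrong,
          error_rate = if (n_asg > 0) n_wrong / n_asg else NA_real_,
          assigned_fraction = n_asg / mixture_size)
      }
    }
  }
  detail <- do.call(rbind, detail)
  agg <- lapply(split(detail, list(detail$threshold, detail$group)),
                function(d) {
    data.frame(threshold = d$threshold[1], group = d$group[1],
               mean_error = if (all(is.na(d$error_rate))) NA_real_ else
                 mean(d$error_rate, na.rm = TRUE),
               sd_error = if (sum(!is.na(d$error_rate)) < 2L) NA_real_ else
                 stats::sd(d$error_rate, na.rm = TRUE),
               mean_assigned_fraction = mean(d$assigned_fraction),
               n_defined = sum(!is.na(d$error_rate)))
  })
  summary <- do.call(rbind, agg)
  summary <- summary[order(summary$threshold, match(summary$group, groups)), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, detail = detail,
                 thresholds = thresholds, groups = groups, config = config),
            class = "gsi_calibration_report")
}

#' @export
print.gsi_calibration_report <- function(x, ...) {
  cat(sprintf("<gsi_calibration_report> %d thresholds x %d groups, %d replicates\n",
              length(x$thresholds), length(x$groups),
              max(x$detail$replicate)))
  print(x$summary)
  invisible(x)
}

#' Pick an assignment threshold from a calibration report
#'
#' Returns the smallest threshold in the evaluated grid whose mean error
#' rate is below `error_ceiling` for every group — i.e. the threshold that
#' maximizes the number of individuals assigned subject to an acceptable
#' incorrect-assignment rate. Groups whose error rate is undefined (no fish
#' ever assigned to them) do not block a threshold. If no threshold
#' satisfies the ceiling, the highest threshold is returned with a warning.
#'
#' @param report A `gsi_calibration_report`.
#' @param error_ceiling Maximum acceptable mean error rate (default 0.15).
#' @return A threshold from the report's grid.
#' @export
choose_threshold <- function(report, error_ceiling = 0.15) {
  stopifnot(inherits(report, "gsi_calibration_report"),
            length(report$thresholds) >= 2L)
  for (th in report$thresholds) {
    errs <- report$summary$mean_error[report$summary$threshold == th]
    if (all(is.na(errs) | errs < error_ceiling)) return(th)
  }
  warning("no threshold meets the error ceiling; returning the highest")
  max(report$thresholds)
}
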