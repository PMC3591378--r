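#' Read a pipeline run configuration
#'
#' Configurations are YAML with the blocks `simulate` (or `inputs`),
#' `preprocess`, `prior`, `chains`, `assignment`, `calibration`,
#' `condition`, plus top-level `seed` and `out_dir`. See
#' [run_pipeline()] for the stage semantics; any omitted block takes the
#' package defaults.
#'
#' @param path YAML file path.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

# Infer locus definitions from a genotype CSV: a column is diploid if every
# non-missing call contains "/", composite otherwise; alphabets are the
# observed symbols.
infer_locus_defs <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character())
  lapply(setdiff(names(df), META_COLS), function(ln) {
    calls <- df[[ln]]
    calls <- calls[!calls %in% c("", MISSING_TOKEN)]
    if (all(grepl("/", calls, fixed = TRUE))) {
      alleles <- sort(unique(unlist(strsplit(calls, "/", fixed = TRUE))))
      locus_def(ln, "diploid_nuclear", alleles)
    } else {
      locus_def(ln, "haploid_composite", sort(unique(calls)))
    }
  })
}

# Give simulated mixture fish lengths (nearest mm) and masses (nearest
# 0.1 g) from group-specific allometries, so the condition stage has
# something to work with: group g gets intercept -5.05 - 0.05*(g-1),
# slope 3.1, mean length 66 + 2*(g-1) mm (SD 6), log10-mass noise 0.04.
attach_condition_traits <- function(records, truth, groups, seed) {
  set.seed(seed)
  g <- match(truth$group, groups)
  n <- nrow(records)
  len <- stats::rnorm(n, 66 + 2 * (g - 1), 6)
  while (any(len <= 0)) {
    len[len <= 0] <- stats::rnorm(sum(len <= 0), 66, 6)
  }
  mass <- 10^(-5.05 - 0.05 * (g - 1) + 3.1 * log10(len) +
                stats::rnorm(n, 0, 0.04))
  df <- as.data.frame(records)
  df$length_mm <- round(len)
  df$mass_g <- pmax(round(mass, 1), 0.1)
  genotype_table(df, table_loci(records))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data loading (or synthetic generation), locus
#' preprocessing, missing-data filtering, the multi-chain mixture MCMC,
#' group-level posterior summaries, threshold-based individual assignment
#' (at the report threshold and, optionally, a sensitivity list of
#' alternative thresholds, each producing a parallel output set), and
#' optionally the holdout calibration and the body-condition model
#' comparison. All artifacts are written under `out_dir` together with a
#' manifest recording the configuration hash, seed, package version,
#' per-stage timings, and a checksum for every output file. Rerunning with
#' an identical configuration reproduces identical numerical outputs.
#'
#' @param config A configuration list (see [read_run_config()]) or a path
#'   to a YAML file.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir %||% "gsimix_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  files <- character()
  timings <- list()
  manifest_path <- file.path(out_dir, "manifest.json")
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      writeLines(paste0("stage '", name, "': ", conditionMessage(e)),
                 failed_marker)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message(sprintf("[gsimix] stage %-12s done (%.1fs)", name,
                    timings[[name]]))
    res
  }

  ## -- load or simulate -----------------------------------------------
  dat <- stage("load", {
    if (!is.null(config$simulate)) {
      sc <- config$simulate
      des <- simulation_design(
        n_populations = sc$n_populations %||% 13L,
        group_sizes = unlist(sc$group_sizes %||%
          c(BlackLake = 5L, ChignikLake = 7L, ChignikRiver = 1L)),
        n_diploid_loci = sc$n_diploid_loci %||% 92L,
        include_composites = sc$include_composites %||% TRUE,
        differentiation = sc$differentiation %||% 0.05,
        baseline_n_per_pop = sc$baseline_n_per_pop %||% 100L,
        seed = seed)
      base <- simulate_baseline(des)
      mix <- simulate_mixture(base$true_freqs, base$group_map,
                              unlist(sc$group_proportions %||%
                                       c(0.25, 0.75, 0)),
                              n = sc$mixture_n %||% 200L,
                              missing_rate = sc$missing_rate %||% 0.002,
                              seed = seed + 1L)
      mix$records <- attach_condition_traits(mix$records, mix$truth,
                                             names(des$group_sizes),
                                             seed + 3L)
      files <- c(files,
        write_genotypes(mix$records,
                        file.path(out_dir, "mixture_genotypes.csv")),
        write_baseline_counts(base$baseline,
                              file.path(out_dir, "baseline_counts.csv")),
        write_tsv(mix$truth, file.path(out_dir, "truth.tsv")))
      list(baseline = base$baseline, mixture = mix$records)
    } else {
      inp <- config$inputs
      loci <- infer_locus_defs(inp$baseline_genotypes)
      base_ind <- read_genotypes(inp$baseline_genotypes, loci)
      group_map <- unlist(inp$group_map)
      baseline <- baseline_from_individuals(base_ind, group_map)
      mixture <- read_genotypes(inp$mixture, loci)
      list(baseline = baseline, mixture = mixture)
    }
  })

  ## -- preprocess + missing-data filter -------------------------------
  pp <- stage("preprocess", {
    pc <- config$preprocess %||% list()
    cfg <- preprocess_config(
      failed_assay = unlist(pc$failed_assay) %||% character(),
      ld_pairs = pc$ld_pairs %||% list(),
      composites = pc$composites %||% list(),
      max_missing_fraction = pc$max_missing_fraction %||% 0.15)
    res <- preprocess_loci(dat$baseline, dat$mixture, cfg)
    fm <- filter_missing(res$mixtures, cfg$max_missing_fraction)
    res$report$individuals_excluded_missing <- data.frame(
      individual_id = names(fm$excluded_fraction),
      missing_fraction = unname(fm$excluded_fraction))
    files <- c(files, write_json_out(
      unclass(res$report), file.path(out_dir, "preprocess_report.json")))
    list(baseline = res$baseline, mixture = fm$retained,
         report = res$report)
  })

  ## -- mixture MCMC ----------------------------------------------------
  cc <- config$chains %||% list()
  draws <- stage("fit_mixture", {
    cfg_chain <- chain_config(
      n_chains = cc$chains %||% 3L,
      iterations = cc$iterations %||% 140000L,
      thin = cc$thin %||% 7L,
      burn_in = cc$burn_in %||% 10000L,
      seed = seed,
      update_allele_freqs = cc$update_allele_freqs %||% TRUE,
      gr_threshold = cc$gr_threshold %||% 1.2)
    pr <- config$prior %||% list()
    prior <- prior_spec(mixture_prior = pr$mixture_prior,
                        allele_prior_scheme = pr$allele_prior_scheme %||%
                          "flat_total")
    run_chains(pp$baseline, pp$mixture, prior, cfg_chain)
  })

  summ <- stage("summaries", {
    s <- summarize_groups(draws)
    theta_tab <- do.call(rbind, lapply(seq_along(draws$theta), function(ci) {
      data.frame(chain = ci, draw = seq_len(nrow(draws$theta[[ci]])),
                 draws$theta[[ci]], check.names = FALSE)
    }))
    files <- c(files,
      write_tsv(theta_tab, file.path(out_dir, "theta_draws.tsv")),
      write_tsv(do.call(rbind, lapply(seq_along(draws$theta), function(ci) {
        g <- group_series(draws)[[ci]]
        data.frame(chain = ci, draw = seq_len(nrow(g)), g,
                   check.names = FALSE)
      })), file.path(out_dir, "group_draws.tsv")),
      write_json_out(as.data.frame(s),
                     file.path(out_dir, "mixture_summary.json")))
    s
  })

  ## -- individual assignment ------------------------------------------
  ac <- config$assignment %||% list()
  report_threshold <- ac$report_threshold %||% 0.8
  sens <- sort(unique(c(report_threshold,
                        unlist(ac$sensitivity_thresholds) %||% numeric())))
  assignments <- stage("assign", {
    post <- individual_posteriors(draws)
    res <- lapply(sens, function(th) {
      asg <- assign_individuals(post, th)
      files <<- c(files, write_tsv(
        asg, file.path(out_dir, sprintf("assignments_%02.0f.tsv", 100 * th))))
      asg
    })
    names(res) <- sprintf("%.2f", sens)
    files <- c(files, write_json_out(
      lapply(res, function(a) as.list(summarize_assignments(a))),
      file.path(out_dir, "assignment_summary.json")))
    res
  })

  ## -- optional holdout calibration -----------------------------------
  if (isTRUE((config$calibration %||% list())$enabled)) {
    stage("calibrate", {
      cal <- config$calibration
      cal_cfg <- chain_config(
        n_chains = cal$chains %||% 1L,
        iterations = cal$iterations %||% 4000L,
        thin = cal$thin %||% 2L,
        burn_in = cal$burn_in %||% 500L,
        seed = seed,
        update_allele_freqs = cc$update_allele_freqs %||% TRUE)
      rep <- holdout_calibration(
        pp$baseline,
        mixture_size = cal$mixture_size %||% 200L,
        group_proportions = unlist(cal$group_proportions %||%
                                     c(0.25, 0.75, 0)),
        n_replicates = cal$n_replicates %||% 10L,
        thresholds = unlist(cal$thresholds) %||% seq(0.5, 0.9, 0.1),
        prior = prior, config = cal_cfg, seed = seed + 2L)
      files <- c(files,
        write_tsv(rep$summary, file.path(out_dir, "calibration_summary.tsv")),
        write_tsv(rep$detail, file.path(out_dir, "calibration_detail.tsv")))
      rep
    })
  }

  ## -- optional condition comparison ----------------------------------
  if (isTRUE((config$condition %||% list())$enabled)) {
    stage("condition", {
      cnd <- config$condition
      res_all <- list()
      for (th in sens) {
        asg <- assignments[[sprintf("%.2f", th)]]
        meta <- as.data.frame(pp$mixture)[c("individual_id", "length_mm",
                                            "mass_g")]
        d <- merge(asg, meta, by = "individual_id")
        grp <- unlist(cnd$groups) %||% pp$baseline$group_levels[1:2]
        d <- d[d$assigned_group %in% grp &
                 !is.na(d$length_mm) & !is.na(d$mass_g), ]
        cd <- condition_data(d$assigned_group, d$length_mm, d$mass_g)
        cmp <- compare_condition(cd, transform = cnd$transform %||% "log10")
        len <- compare_lengths(cd, alpha = cnd$alpha %||% 0.05)
        files <- c(files, write_tsv(
          as.data.frame(cmp)[c("model", "delta_aicc", "weight")],
          file.path(out_dir, sprintf("condition_%02.0f.tsv", 100 * th))))
        res_all[[sprintf("%.2f", th)]] <- list(
          models = as.data.frame(cmp),
          lengths = len[c("bartlett_stat", "bartlett_p", "chosen_test",
                          "statistic", "p_value")])
      }
      files <- c(files, write_json_out(
        res_all, file.path(out_dir, "condition.json")))
      res_all
    })
  }

  ## -- manifest --------------------------------------------------------
  manifest <- list(
    package = "gsimix",
    version = as.character(utils::packageVersion("gsimix")),
    seed = seed,
    config_md5 = digest_config(config),
    stages = timings,
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      unname(tools::md5sum(f))
    }))
  write_json_out(manifest, manifest_path)
  invisible(manifest)
}

digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}
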