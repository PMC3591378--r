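#' Preprocessing configuration
#'
#' Settings for [preprocess_loci()]: loci whose assay failed, linkage
#' pairs with the member designated for removal, and composite groupings
#' that join several raw markers into one haploid or phenotype locus.
#'
#' @param failed_assay Character vector of loci to drop because genotyping
#'   failed.
#' @param ld_pairs List of length-2 character vectors `c(drop, keep)`;
#'   the first member of each pair is removed.
#' @param composites List of `list(name=, members=, mode=)` where `mode` is
#'   `"haploid_composite"` (e.g. joined mitochondrial SNPs) or
#'   `"phenotype_composite"` (e.g. a joint two-locus MHC genotype class).
#' @param max_missing_fraction Per-individual missing-call fraction at or
#'   above which an individual is excluded by [filter_missing()].
#' @return A list of class `gsi_preprocess_config`.
#' @export
preprocess_config <- function(failed_assay = character(),
                              ld_pairs = list(),
                              composites = list(),
                              max_missing_fraction = 0.15) {
  stopifnot(max_missing_fraction > 0, max_missing_fraction <= 1)
  for (p in ld_pairs) stopifnot(length(p) == 2L)
  for (cmp in composites) {
    stopifnot(all(c("name", "members", "mode") %in% names(cmp)),
              cmp$mode %in% c("haploid_composite", "phenotype_composite"),
              length(cmp$members) >= 2L)
  }
  structure(list(failed_assay = failed_assay, ld_pairs = ld_pairs,
                 composites = composites,
                 max_missing_fraction = max_missing_fraction),
            class = "gsi_preprocess_config")
}

# Join member-locus calls into a composite category; MISSING if any member
# call is missing (no partial haplotypes are invented).
composite_calls <- function(tbl, members) {
  parts <- lapply(members, function(m) tbl[[m]])
  out <- do.call(paste, c(parts, sep = "-"))
  any_na <- Reduce(`|`, lapply(parts, is.na))
  out[any_na] <- NA_character_
  out
}

#' Preprocess baseline and mixture loci
#'
#' Applies the locus-handling rules used before any stock-identification
#' inference, in order: (1) drop failed-assay loci, (2) drop loci that are
#' monomorphic across all baseline populations (mixture-only variation does
#' not retain a locus), (3) drop the designated member of each linkage
#' pair, (4) replace each composite grouping's member loci by a single
#' composite locus whose categories are the joint classes observed in the
#' data (a haploid composite for jointly inherited markers; a phenotype
#' composite for a joint multi-locus genotype class). Composite construction
#' needs individual-level baseline genotypes, since joint categories cannot
#' be recovered from per-locus allele counts.
#'
#' The function is idempotent: rules referring to loci no longer present are
#' skipped, so a second application returns identical data and an empty
#' report.
#'
#' @param baseline A [baseline_set()].
#' @param mixtures A [genotype_table()] of mixture individuals sharing the
#'   baseline's loci.
#' @param config A [preprocess_config()].
#' @return List with elements `baseline`, `mixtures`, and `report` (class
#'   `gsi_preprocess_report`).
#' @export
preprocess_loci <- function(baseline, mixtures, config = preprocess_config()) {
  stopifnot(inherits(baseline, "gsi_baseline"),
            inherits(mixtures, "gsi_genotypes"),
            inherits(config, "gsi_preprocess_config"))
  loci <- baseline$loci
  present <- names(loci)
  if (!setequal(present, names(table_loci(mixtures)))) {
    stop("baseline and mixture loci differ", call. = FALSE)
  }

  dropped_failed <- intersect(config$failed_assay, present)

  # monomorphism judged on the pooled baseline counts only
  pooled <- stats::aggregate(count ~ locus + allele, data = baseline$counts,
                             FUN = sum)
  n_seg <- tapply(pooled$count > 0, pooled$locus, sum)
  dropped_mono <- setdiff(names(n_seg)[n_seg <= 1L], dropped_failed)
  dropped_mono <- intersect(present, dropped_mono)

  dropped_ld <- character()
  for (p in config$ld_pairs) {
    drop <- p[[1]]
    if (drop %in% setdiff(present, c(dropped_failed, dropped_mono))) {
      dropped_ld <- c(dropped_ld, drop)
    }
  }
  dropped <- c(dropped_failed, dropped_mono, dropped_ld)
  kept <- setdiff(present, dropped)

  composites_created <- character()
  comp_specs <- list()
  for (cmp in config$composites) {
    if (cmp$name %in% kept) next  # already built (idempotent rerun)
    n_present <- sum(cmp$members %in% kept)
    if (n_present == 0L) next
    bad <- intersect(cmp$members, dropped)
    if (length(bad)) {
      stop("composite '", cmp$name, "' references dropped locus/loci: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (n_present < length(cmp$members)) {
      stop("composite '", cmp$name, "' references unknown locus/loci",
           call. = FALSE)
    }
    comp_specs[[cmp$name]] <- cmp
    composites_created <- c(composites_created, cmp$name)
  }
  if (length(comp_specs) && is.null(baseline$individuals)) {
    stop("composite construction requires individual-level baseline ",
         "genotypes", call. = FALSE)
  }

  transform_table <- function(tbl, new_alphabets = NULL) {
    df <- as.data.frame(tbl)
    old_loci <- table_loci(tbl)
    order_names <- names(old_loci)
    new_loci <- list()
    new_cols <- list()
    consumed <- unlist(lapply(comp_specs, `[[`, "members"))
    for (ln in order_names) {
      if (ln %in% dropped || ln %in% consumed) {
        # composite replaces its first member in column order
        for (nm in names(comp_specs)) {
          cmp <- comp_specs[[nm]]
          if (identical(ln, cmp$members[[1]])) {
            calls <- composite_calls(df, cmp$members)
            new_cols[[nm]] <- calls
            cats <- if (is.null(new_alphabets)) sort(unique(calls[!is.na(calls)]))
                    else new_alphabets[[nm]]
            new_loci[[nm]] <- locus_def(nm, cmp$mode, cats)
          }
        }
        next
      }
      new_cols[[ln]] <- df[[ln]]
      new_loci[[ln]] <- old_loci[[ln]]
    }
    out <- df[intersect(META_COLS, names(df))]
    for (nm in names(new_cols)) out[[nm]] <- new_cols[[nm]]
    genotype_table(out, new_loci[names(new_cols)])
  }

  # composite alphabets = joint classes observed in baseline or mixture
  alphabets <- NULL
  if (length(comp_specs)) {
    alphabets <- lapply(comp_specs, function(cmp) {
      b <- composite_calls(as.data.frame(baseline$individuals), cmp$members)
      m <- composite_calls(as.data.frame(mixtures), cmp$members)
      sort(unique(c(b[!is.na(b)], m[!is.na(m)])))
    })
  }

  mixtures_out <- transform_table(mixtures, alphabets)

  if (!is.null(baseline$individuals)) {
    base_ind <- transform_table(baseline$individuals, alphabets)
    baseline_out <- baseline_from_individuals(base_ind, baseline$group_map)
  } else {
    counts <- baseline$counts[baseline$counts$locus %in% kept, , drop = FALSE]
    rownames(counts) <- NULL
    baseline_out <- baseline_set(counts, baseline$group_map, loci[kept])
  }

  report <- structure(list(
    loci_dropped_monomorphic = dropped_mono,
    loci_dropped_ld = dropped_ld,
    loci_dropped_failed_assay = dropped_failed,
    composites_created = composites_created,
    individuals_excluded_missing = data.frame(individual_id = character(),
                                              missing_fraction = numeric())),
    class = "gsi_preprocess_report")
  stopifnot(!anyDuplicated(c(dropped, composites_created)))
  list(baseline = baseline_out, mixtures = mixtures_out, report = report)
}

#' @export
print.gsi_preprocess_report <- function(x, ...) {
  cat("<gsi_preprocess_report>\n",
      "  monomorphic dropped: ", paste(x$loci_dropped_monomorphic, collapse = ", "), "\n",
      "  LD member dropped:   ", paste(x$loci_dropped_ld, collapse = ", "), "\n",
      "  failed assay:        ", paste(x$loci_dropped_failed_assay, collapse = ", "), "\n",
      "  composites created:  ", paste(x$composites_created, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Exclude individuals with too many missing genotypes
#'
#' An individual is excluded if and only if its fraction of missing calls,
#' `(# MISSING) / (# loci)`, is at least `max_missing_fraction` — the
#' comparison is inclusive ("at least 15% of the loci").
#'
#' @param records A [genotype_table()].
#' @param max_missing_fraction Proportion in (0, 1]; default 0.15.
#' @return List with `retained` and `excluded` genotype tables and
#'   `excluded_fraction`, a named numeric of missing fractions for the
#'   excluded individuals. Retained and excluded partition the input.
#' @export
filter_missing <- function(records, max_missing_fraction = 0.15) {
  stopifnot(inherits(records, "gsi_genotypes"),
            max_missing_fraction > 0, max_missing_fraction <= 1)
  loci <- table_loci(records)
  if (length(loci) == 0L) stop("empty locus set", call. = FALSE)
  call_mat <- as.matrix(as.data.frame(records)[names(loci)])
  frac <- rowMeans(is.na(call_mat))
  drop <- frac >= max_missing_fraction
  list(retained = subset_genotypes(records, !drop),
       excluded = subset_genotypes(records, drop),
       excluded_fraction = stats::setNames(frac[drop],
                                           records$individual_id[drop]))
}
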