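META_COLS <- c("individual_id", "population", "year", "site",
               "length_mm", "mass_g")

#' Construct a genotype table
#'
#' The package's central genotype container: a `data.frame` with one row per
#' individual, optional metadata columns (`population`, `year`, `site`,
#' `length_mm`, `mass_g`), and one character column per locus holding
#' canonical calls. Diploid calls are unordered allele pairs written
#' `"A/C"` (canonicalized lexicographically, so `"C/A"` is stored as
#' `"A/C"`); composite calls are single category tokens; missing calls are
#' `NA`.
#'
#' @param df Data frame with an `individual_id` column, optional metadata
#'   columns, and one column per locus.
#' @param loci List of [locus_def()] objects, one per locus column in `df`.
#' @return A `gsi_genotypes` data frame with a `loci` attribute.
#' @export
genotype_table <- function(df, loci) {
  stopifnot(is.data.frame(df))
  names(loci) <- locus_names(loci)
  if (!"individual_id" %in% names(df)) {
    stop("genotype table needs an 'individual_id' column", call. = FALSE)
  }
  if (anyDuplicated(df$individual_id)) {
    stop("duplicated individual_id values", call. = FALSE)
  }
  locus_cols <- setdiff(names(df), META_COLS)
  unknown <- setdiff(locus_cols, names(loci))
  if (length(unknown)) {
    stop("unknown locus column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(names(loci), locus_cols)
  if (length(absent)) {
    stop("loci missing from table: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  for (m in c("length_mm", "mass_g")) {
    if (m %in% names(df)) {
      v <- df[[m]]
      if (any(!is.na(v) & v <= 0)) {
        stop(m, " must be > 0 when present", call. = FALSE)
      }
    }
  }
  for (ln in names(loci)) {
    df[[ln]] <- canonicalize_column(as.character(df[[ln]]), loci[[ln]])
  }
  df <- df[c(intersect(META_COLS, names(df)), names(loci))]
  structure(df, loci = loci, class = c("gsi_genotypes", "data.frame"))
}

#' @export
print.gsi_genotypes <- function(x, ...) {
  loci <- attr(x, "loci")
  cat(sprintf("<gsi_genotypes> %d individuals x %d loci\n", nrow(x),
              length(loci)))
  NextMethod()
}

#' @rdname genotype_table
#' @param x A `gsi_genotypes` table.
#' @export
table_loci <- function(x) attr(x, "loci")

# Subset rows keeping the class/attributes intact.
subset_genotypes <- function(x, idx) {
  out <- as.data.frame(x)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, loci = attr(x, "loci"),
            class = c("gsi_genotypes", "data.frame"))
}

#' Read a genotype CSV
#'
#' Reads the package's genotype CSV dialect: a header
#' `individual_id,population,year,site,length_mm,mass_g,<locus1>,...`
#' (metadata columns other than `individual_id` optional), diploid calls as
#' `X/Y`, composite calls as single tokens, and `-` (or empty) marking a
#' missing call. Calls whose symbols fall outside the locus alphabet raise a
#' parse error naming the row and column.
#'
#' @param path CSV file path.
#' @param locus_defs List of [locus_def()] objects describing every locus
#'   column present in the file.
#' @return A [genotype_table()].
#' @examples
#' loci <- list(locus_def("snp1", "diploid_nuclear", c("A", "C")),
#'              locus_def("snp2", "diploid_nuclear", c("G", "T")),
#'              locus_def("mt", "haploid_composite", c("H1", "H2")))
#' read_genotypes(system.file("extdata", "toy_mixture.csv",
#'                            package = "gsimix"), loci)
#' @export
read_genotypes <- function(path, locus_defs) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = character())
  if (!"individual_id" %in% names(df)) {
    stop("malformed header: no 'individual_id' column in ", path,
         call. = FALSE)
  }
  names(locus_defs) <- locus_names(locus_defs)
  locus_cols <- setdiff(names(df), META_COLS)
  unknown <- setdiff(locus_cols, names(locus_defs))
  if (length(unknown)) {
    stop("unknown locus column(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (m in c("length_mm", "mass_g")) {
    if (m %in% names(df)) df[[m]] <- as.numeric(ifelse(df[[m]] == "", NA, df[[m]]))
  }
  if ("year" %in% names(df)) df$year <- as.integer(ifelse(df$year == "", NA, df$year))
  for (ln in locus_cols) df[[ln]][df[[ln]] == ""] <- MISSING_TOKEN
  genotype_table(df, locus_defs[locus_cols])
}

#' Write a genotype table as CSV
#'
#' Inverse of [read_genotypes()]: missing calls are written as `-`.
#'
#' @param x A [genotype_table()].
#' @param path Output CSV path.
#' @export
write_genotypes <- function(x, path) {
  df <- as.data.frame(x)
  for (ln in names(table_loci(x))) {
    df[[ln]][is.na(df[[ln]])] <- MISSING_TOKEN
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GenePop file (diploid loci only)
#'
#' Convenience reader for the standard GenePop format: a title line, one
#' locus name per line (or a single comma-separated line), `Pop` separators,
#' and per-individual lines `id , 0101 0202 ...` with 2- or 3-digit allele
#' codes; `0000`/`000000` marks a missing genotype. Allele codes are kept as
#' integer-string symbols (`"1"`, `"2"`, ...). Populations are labelled by
#' the identifier of the last individual in each `Pop` block, the usual
#' GenePop convention.
#'
#' @param path GenePop file path.
#' @return A [genotype_table()] with a `population` column.
#' @examples
#' read_genepop(system.file("extdata", "toy.gen", package = "gsimix"))
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L) stop("malformed GenePop file: ", path, call. = FALSE)
  body <- lines[-1]
  pop_idx <- grep("^pop$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("GenePop file has no 'Pop' line", call. = FALSE)
  locus_lines <- body[seq_len(pop_idx[1] - 1L)]
  loci_names <- unlist(strsplit(paste(locus_lines, collapse = ","), ","))
  loci_names <- trimws(loci_names)
  loci_names <- loci_names[nzchar(loci_names)]
  ind_lines <- body[-seq_len(pop_idx[1] - 1L)]
  pop_breaks <- grepl("^pop$", ind_lines, ignore.case = TRUE)
  pop_no <- cumsum(pop_breaks)
  ind_lines <- ind_lines[!pop_breaks]
  pop_no <- pop_no[!pop_breaks]

  rows <- lapply(seq_along(ind_lines), function(i) {
    parts <- strsplit(ind_lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("malformed GenePop individual line: ", ind_lines[i], call. = FALSE)
    }
    id <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    if (length(codes) != length(loci_names)) {
      stop("individual '", id, "': expected ", length(loci_names),
           " genotypes, found ", length(codes), call. = FALSE)
    }
    calls <- vapply(codes, function(code) {
      w <- nchar(code) / 2L
      if (!w %in% c(2L, 3L)) {
        stop("bad GenePop genotype code '", code, "'", call. = FALSE)
      }
      a1 <- as.integer(substr(code, 1L, w))
      a2 <- as.integer(substr(code, w + 1L, 2L * w))
      if (a1 == 0L || a2 == 0L) return(NA_character_)
      paste(sort(c(a1, a2)), collapse = "/")
    }, character(1), USE.NAMES = FALSE)
    c(id = id, calls)
  })
  mat <- do.call(rbind, rows)
  df <- data.frame(individual_id = mat[, 1],
                   population = paste0("pop_", pop_no),
                   check.names = FALSE)
  # population label: last individual id of each block (GenePop convention)
  last_ids <- tapply(mat[, 1], pop_no, function(v) v[length(v)])
  df$population <- unname(last_ids[as.character(pop_no)])
  for (j in seq_along(loci_names)) df[[loci_names[j]]] <- mat[, j + 1L]
  loci <- lapply(loci_names, function(ln) {
    obs <- df[[ln]][!is.na(df[[ln]])]
    alleles <- sort(unique(unlist(strsplit(obs, "/", fixed = TRUE))))
    if (!length(alleles)) alleles <- "1"
    locus_def(ln, "diploid_nuclear", alleles)
  })
  genotype_table(df, loci)
}

#' Construct a baseline set
#'
#' A baseline is the reference side of a mixed-stock analysis: per-population,
#' per-locus allele (or category) counts together with a map from population
#' to reporting stock group. Individual-level baseline genotypes may be
#' attached; they are required for composite-locus construction and for the
#' holdout calibration, which removes individuals from the baseline.
#'
#' @param counts Data frame with columns
#'   `population, stock_group, locus, allele, count` (non-negative integers).
#' @param group_map Named character vector, `population -> stock group`.
#'   Group labels form a fixed ordered set, in order of first appearance.
#' @param loci List of [locus_def()] objects covering every locus in `counts`.
#' @param individuals Optional [genotype_table()] with a `population` column.
#' @return A `gsi_baseline` object.
#' @export
baseline_set <- function(counts, group_map, loci, individuals = NULL) {
  stopifnot(is.data.frame(counts))
  need <- c("population", "stock_group", "locus", "allele", "count")
  if (!all(need %in% names(counts))) {
    stop("baseline counts need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    stop("baseline counts must be non-negative integers", call. = FALSE)
  }
  pops <- unique(counts$population)
  missing_pop <- setdiff(pops, names(group_map))
  if (length(missing_pop)) {
    stop("population(s) absent from group_map: ",
         paste(missing_pop, collapse = ", "), call. = FALSE)
  }
  bad_group <- counts$stock_group != unname(group_map[counts$population])
  if (any(bad_group)) stop("counts stock_group disagrees with group_map",
                           call. = FALSE)
  names(loci) <- locus_names(loci)
  unknown <- setdiff(unique(counts$locus), names(loci))
  if (length(unknown)) {
    stop("counts reference unknown loci: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(individuals)) {
    stopifnot(inherits(individuals, "gsi_genotypes"))
    if (!"population" %in% names(individuals)) {
      stop("baseline individuals need a 'population' column", call. = FALSE)
    }
  }
  structure(list(counts = counts,
                 group_map = group_map,
                 group_levels = unique(unname(group_map)),
                 populations = names(group_map),
                 loci = loci,
                 individuals = individuals),
            class = "gsi_baseline")
}

#' @export
print.gsi_baseline <- function(x, ...) {
  cat(sprintf("<gsi_baseline> %d populations in %d groups, %d loci%s\n",
              length(x$populations), length(x$group_levels), length(x$loci),
              if (is.null(x$individuals)) "" else
                sprintf(", %d baseline individuals", nrow(x$individuals))))
  invisible(x)
}

#' Tally a baseline from individual genotypes
#'
#' @param individuals A [genotype_table()] with a `population` column.
#' @param group_map Named character vector `population -> stock group`.
#' @return A [baseline_set()] whose counts are the observed allele/category
#'   tallies and which retains the individuals.
#' @export
baseline_from_individuals <- function(individuals, group_map) {
  stopifnot(inherits(individuals, "gsi_genotypes"))
  loci <- table_loci(individuals)
  pops <- names(group_map)
  rows <- list()
  for (pop in pops) {
    sub <- individuals[individuals$population == pop, , drop = FALSE]
    for (ln in names(loci)) {
      locus <- loci[[ln]]
      calls <- sub[[ln]]
      calls <- calls[!is.na(calls)]
      if (is_diploid(locus)) {
        obs <- unlist(strsplit(calls, "/", fixed = TRUE))
      } else {
        obs <- calls
      }
      tab <- table(factor(obs, levels = locus$alleles))
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, stock_group = unname(group_map[pop]),
        locus = ln, allele = locus$alleles,
        count = as.integer(tab), check.names = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  baseline_set(counts, group_map, loci, individuals = individuals)
}

#' Read baseline allele counts from CSV
#'
#' @param path CSV with columns `population,stock_group,locus,allele,count`.
#' @param loci Optional list of [locus_def()]; if omitted, every locus is
#'   assumed diploid nuclear with the alphabet observed in the file.
#' @param group_map Optional named map `population -> stock group`; derived
#'   from the file's `stock_group` column when omitted.
#' @return A [baseline_set()].
#' @export
read_baseline_counts <- function(path, loci = NULL, group_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  counts <- utils::read.csv(path, check.names = FALSE,
                            colClasses = c(count = "integer"))
  if (is.null(group_map)) {
    first <- !duplicated(counts$population)
    group_map <- stats::setNames(counts$stock_group[first],
                                 counts$population[first])
  }
  if (is.null(loci)) {
    loci <- lapply(split(counts, counts$locus), function(d) {
      locus_def(d$locus[1], "diploid_nuclear", unique(d$allele))
    })
    loci <- loci[unique(counts$locus)]  # preserve file order
  }
  baseline_set(counts, group_map, loci)
}

#' Write baseline counts as CSV
#' @param baseline A [baseline_set()].
#' @param path Output path.
#' @export
write_baseline_counts <- function(baseline, path) {
  utils::write.csv(baseline$counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
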