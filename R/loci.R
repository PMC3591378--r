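#' Define a marker locus
#'
#' A locus is a single genetic marker together with its inheritance mode and
#' the alphabet of symbols that genotype calls at that locus may use. Three
#' modes are supported: ordinary diploid nuclear SNPs (`diploid_nuclear`,
#' unordered two-allele calls), composite haploid markers such as a joined
#' mitochondrial haplotype (`haploid_composite`, one category per call), and
#' composite phenotype markers such as a joint two-locus MHC genotype class
#' (`phenotype_composite`, one category per call).
#'
#' @param name Marker identifier, a single non-empty string.
#' @param mode One of `"diploid_nuclear"`, `"haploid_composite"`,
#'   `"phenotype_composite"`.
#' @param alleles Character vector of allele or category symbols; must be
#'   non-empty and unique. A single symbol (monomorphic locus) is allowed
#'   before filtering.
#' @return An object of class `gsi_locus`.
#' @examples
#' locus_def("One_MHC2_190", "diploid_nuclear", c("A", "C"))
#' @export
locus_def <- function(name, mode = c("diploid_nuclear", "haploid_composite",
                                     "phenotype_composite"),
                      alleles) {
  mode <- match.arg(mode)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  alleles <- as.character(alleles)
  if (length(alleles) < 1L) {
    stop("locus '", name, "': allele alphabet must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(alleles)) {
    stop("locus '", name, "': duplicated allele symbols", call. = FALSE)
  }
  structure(list(name = name, mode = mode, alleles = alleles),
            class = "gsi_locus")
}

#' @export
print.gsi_locus <- function(x, ...) {
  cat(sprintf("<gsi_locus> %s [%s] alleles: %s\n",
              x$name, x$mode, paste(x$alleles, collapse = ", ")))
  invisible(x)
}

is_diploid <- function(locus) locus$mode == "diploid_nuclear"

#' @keywords internal
locus_names <- function(loci) vapply(loci, `[[`, character(1), "name")

# Canonical string for one call at a locus: diploid calls are unordered, so
# "C/A" and "A/C" both become "A/C"; composite calls are single tokens.
canonicalize_call <- function(call, locus) {
  if (is.na(call) || call == "" || call == MISSING_TOKEN) return(NA_character_)
  if (is_diploid(locus)) {
    parts <- strsplit(call, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("locus '", locus$name, "': diploid call '", call,
           "' is not of the form X/Y", call. = FALSE)
    }
    bad <- setdiff(parts, locus$alleles)
    if (length(bad)) {
      stop("locus '", locus$name, "': allele symbol(s) ",
           paste(sQuote(bad), collapse = ", "), " outside alphabet",
           call. = FALSE)
    }
    paste(sort(parts), collapse = "/")
  } else {
    if (!call %in% locus$alleles) {
      stop("locus '", locus$name, "': category '", call,
           "' outside alphabet", call. = FALSE)
    }
    call
  }
}

MISSING_TOKEN <- "-"

# Vectorized canonicalization of a whole locus column; errors name the
# offending row and column.
canonicalize_column <- function(calls, locus) {
  out <- calls
  out[is.na(out) | out == "" | out == MISSING_TOKEN] <- NA_character_
  obs <- which(!is.na(out))
  if (!length(obs)) return(out)
  if (is_diploid(locus)) {
    parts <- strsplit(out[obs], "/", fixed = TRUE)
    n_part <- lengths(parts)
    if (any(n_part != 2L)) {
      i <- obs[which(n_part != 2L)[1]]
      stop("row ", i, ", column '", locus$name, "': diploid call '",
           calls[i], "' is not of the form X/Y", call. = FALSE)
    }
    a1 <- vapply(parts, `[`, character(1), 1L)
    a2 <- vapply(parts, `[`, character(1), 2L)
    bad <- !(a1 %in% locus$alleles) | !(a2 %in% locus$alleles)
    if (any(bad)) {
      i <- obs[which(bad)[1]]
      stop("row ", i, ", column '", locus$name, "': allele symbol in '",
           calls[i], "' outside alphabet", call. = FALSE)
    }
    out[obs] <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  } else {
    bad <- !(out[obs] %in% locus$alleles)
    if (any(bad)) {
      i <- obs[which(bad)[1]]
      stop("row ", i, ", column '", locus$name, "': category '", calls[i],
           "' outside alphabet", call. = FALSE)
    }
  }
  out
}

# Split a canonical diploid call into its two allele symbols.
call_alleles <- function(call) strsplit(call, "/", fixed = TRUE)[[1]]
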