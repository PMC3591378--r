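# Internal numeric encoding shared by the likelihood and the Gibbs sampler.
#
# Loci are laid out as a block of columns per locus: one column per allele
# (diploid) or per category (composite). A genotype table becomes an
# n x C matrix of allele copy counts (0/1/2 for diploid loci, 0/1 for
# composites); a baseline becomes a C x K count matrix. Per-fish,
# per-population log-likelihoods are then X %*% log(P) plus a
# heterozygosity constant that is shared across populations (and therefore
# omitted inside the sampler, where only relative weights matter).

allele_layout <- function(loci) {
  names(loci) <- locus_names(loci)
  locus <- integer(0); allele <- character(0); locus_name <- character(0)
  for (j in seq_along(loci)) {
    a <- loci[[j]]$alleles
    locus <- c(locus, rep.int(j, length(a)))
    allele <- c(allele, a)
    locus_name <- c(locus_name, rep.int(names(loci)[j], length(a)))
  }
  list(loci = loci, n_loci = length(loci), block = locus,
       allele = allele, locus_name = locus_name,
       col = stats::setNames(seq_along(allele),
                             paste(locus_name, allele, sep = "\r")))
}

layout_col <- function(layout, locus, allele) {
  layout$col[[paste(locus, allele, sep = "\r")]]
}

# n x C allele copy counts; attr "n_het" = per-fish heterozygous diploid
# call count (the log(2) likelihood constant), attr "n_obs" = non-missing
# call count.
encode_genotypes <- function(tbl, layout) {
  loci <- layout$loci
  n <- nrow(tbl)
  X <- matrix(0, n, length(layout$allele))
  n_het <- integer(n)
  n_obs <- integer(n)
  df <- as.data.frame(tbl)
  for (ln in names(loci)) {
    locus <- loci[[ln]]
    calls <- df[[ln]]
    ok <- !is.na(calls)
    n_obs <- n_obs + ok
    if (!any(ok)) next
    if (is_diploid(locus)) {
      parts <- strsplit(calls[ok], "/", fixed = TRUE)
      a1 <- vapply(parts, `[`, character(1), 1L)
      a2 <- vapply(parts, `[`, character(1), 2L)
      i1 <- vapply(a1, function(a) layout_col(layout, ln, a), numeric(1))
      i2 <- vapply(a2, function(a) layout_col(layout, ln, a), numeric(1))
      rows <- which(ok)
      X[cbind(rows, i1)] <- X[cbind(rows, i1)] + 1
      X[cbind(rows, i2)] <- X[cbind(rows, i2)] + 1
      n_het[rows] <- n_het[rows] + (a1 != a2)
    } else {
      idx <- vapply(calls[ok], function(a) layout_col(layout, ln, a),
                    numeric(1))
      X[cbind(which(ok), idx)] <- 1
    }
  }
  attr(X, "n_het") <- n_het
  attr(X, "n_obs") <- n_obs
  X
}

# C x K baseline count matrix, populations in baseline$populations order.
baseline_count_matrix <- function(baseline, layout) {
  pops <- baseline$populations
  M <- matrix(0, length(layout$allele), length(pops),
              dimnames = list(NULL, pops))
  cts <- baseline$counts
  idx <- vapply(seq_len(nrow(cts)),
                function(i) layout_col(layout, cts$locus[i], cts$allele[i]),
                numeric(1))
  k <- match(cts$population, pops)
  for (i in seq_len(nrow(cts))) M[idx[i], k[i]] <- M[idx[i], k[i]] + cts$count[i]
  M
}

# Dirichlet pseudocounts for allele frequencies. "flat_total": 1/A_l per
# allele at a locus with A_l alleles (the flat-total convention of the
# conditional GSI model family); "unit": 1 per allele.
allele_pseudocounts <- function(layout, scheme = c("flat_total", "unit")) {
  scheme <- match.arg(scheme)
  block_sizes <- tabulate(layout$block, nbins = layout$n_loci)
  if (scheme == "flat_total") 1 / block_sizes[layout$block] else
    rep(1, length(layout$block))
}

# Normalize a C x K (or C-vector) count matrix to frequencies within each
# locus block.
normalize_blocks <- function(M, layout) {
  M <- as.matrix(M)
  out <- M
  for (j in seq_len(layout$n_loci)) {
    rows <- layout$block == j
    s <- colSums(M[rows, , drop = FALSE])
    out[rows, ] <- sweep(M[rows, , drop = FALSE], 2, s, "/")
  }
  out
}

#' Posterior-mean baseline allele frequencies
#'
#' Per population and locus, the Dirichlet posterior mean
#' `(count + pseudocount) / (total + total pseudocount)` given the baseline
#' allele counts and the allele prior. These are the frequencies the
#' sampler conditions on when allele-frequency updating is switched off.
#'
#' @param baseline A [baseline_set()].
#' @param prior A [prior_spec()].
#' @return Named list per population; each element a named list per locus of
#'   named frequency vectors.
#' @export
baseline_posterior_freqs <- function(baseline, prior = prior_spec()) {
  layout <- allele_layout(baseline$loci)
  B <- baseline_count_matrix(baseline, layout)
  P <- normalize_blocks(B + allele_pseudocounts(layout, prior$allele_prior_scheme),
                        layout)
  lapply(stats::setNames(seq_len(ncol(P)), colnames(P)), function(k) {
    lapply(stats::setNames(seq_len(layout$n_loci),
                           names(layout$loci)), function(j) {
      rows <- layout$block == j
      stats::setNames(P[rows, k], layout$allele[rows])
    })
  })
}

# Flatten a per-population freq list (as produced by
# baseline_posterior_freqs) back to a C x K matrix for the sampler.
freqs_to_matrix <- function(freqs, layout) {
  K <- length(freqs)
  P <- matrix(0, length(layout$allele), K, dimnames = list(NULL, names(freqs)))
  for (k in seq_len(K)) {
    for (j in seq_len(layout$n_loci)) {
      rows <- which(layout$block == j)
      v <- freqs[[k]][[names(layout$loci)[j]]]
      P[rows, k] <- unname(v[layout$allele[rows]])
    }
  }
  P
}
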