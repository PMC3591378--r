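#!/usr/bin/env Rscript
# Generate the synthetic study data: a 13-population baseline with known
# allele frequencies and a 200-fish mixture at 25% Black Lake / 75% Chignik
# Lake / 0% Chignik River, with lengths and masses attached.

source("analysis/00_params.R")

dat <- simulated_data()

write_baseline_counts(dat$base$baseline, out_path("data", "baseline_counts.csv"))
write_genotypes(dat$base$baseline$individuals,
                out_path("data", "baseline_genotypes.csv"))
write_genotypes(dat$mix$records, out_path("data", "mixture_genotypes.csv"))
write.table(dat$mix$truth, out_path("data", "truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("baseline: %d populations, %d loci, %d individuals/population\n",
            length(dat$base$baseline$populations),
            length(dat$base$baseline$loci), design$baseline_n_per_pop))
tab <- table(dat$mix$truth$group)
cat("mixture composition (true origins):\n")
print(tab)
n_miss <- sum(is.na(as.data.frame(dat$mix$records)[
  names(table_loci(dat$mix$records))]))
cat(sprintf("missing calls in mixture: %d (%.2f%% of calls)\n", n_miss,
            100 * n_miss / (MIXTURE_N * length(table_loci(dat$mix$records)))))
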