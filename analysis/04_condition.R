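#!/usr/bin/env Rscript
# Body-condition analysis of the assigned fish: Bartlett-gated length
# comparison, then the four nested length-mass regressions compared by AICc
# and Akaike weights, at each report threshold.

source("analysis/00_params.R")

dat <- simulated_data()
meta <- as.data.frame(dat$mix$records)[c("individual_id", "length_mm",
                                         "mass_g")]

for (th in REPORT_THRESHOLDS) {
  f <- file.path(RESULTS, "assignment",
                 sprintf("assignments_%02.0f.tsv", 100 * th))
  if (!file.exists(f)) {
    stop("run analysis/03_assignment_calibration.R first (missing ", f, ")")
  }
  asg <- read.delim(f)
  d <- merge(asg, meta, by = "individual_id")
  d <- d[d$assigned_group %in% c("BlackLake", "ChignikLake"), ]
  cd <- condition_data(d$assigned_group, d$length_mm, d$mass_g)

  len <- compare_lengths(cd, alpha = 0.05)
  cmp <- compare_condition(cd, transform = "log10")

  write.table(as.data.frame(cmp)[c("model", "delta_aicc", "weight")],
              out_path("condition", sprintf("condition_%02.0f.tsv", 100 * th)),
              sep = "\t", row.names = FALSE, quote = FALSE)

  cat(sprintf("\n== threshold %.0f%% (n = %d assigned fish) ==\n", 100 * th,
              nrow(cd)))
  cat(sprintf("lengths: Bartlett p = %.3g -> %s, statistic = %.3f, p = %.3g\n",
              len$bartlett_p, len$chosen_test, len$statistic, len$p_value))
  print(as.data.frame(cmp)[c("model", "k", "aicc", "delta_aicc", "weight")],
        digits = 3)
}
jsonlite::write_json(
  list(note = paste("condition comparisons on fish assigned at each",
                    "threshold; groups are assigned stock groups")),
  out_path("condition", "README.json"), auto_unbox = TRUE)
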