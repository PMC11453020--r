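#!/usr/bin/env Rscript
# Step 5 — presence-frequency selection scans.
#
# Per gene, a 2x2 presence/absence table between two populations is tested
# with a two-sided Fisher exact test; genes at raw P < 0.005 are labelled
# favorable (higher frequency in the derived population) or unfavorable
# (lower). Two comparisons mirror the domestication and improvement axes:
# wild -> native, and native -> improved.

suppressPackageStartupMessages({
  library(pavkit)
  library(data.table)
})

m <- read_presence_matrix("results/presence_matrix.tsv")
popmap <- read_population_map("scratch/cohort/popmap.tsv")

run_scan <- function(ref, der, label) {
  res <- scan_selection(m, popmap, scan_config(ref, der, alpha = 0.005))
  fwrite(res, sprintf("results/scan_%s.tsv", label), sep = "\t")
  ds <- direction_summary(res)
  cat(sprintf("%s (%s -> %s): %d significant genes", label, ref, der,
              ds$n_significant))
  if (ds$n_significant > 0) {
    cat(sprintf(" — %d favorable, %d unfavorable (%.2f%% unfavorable)",
                ds$n_favorable, ds$n_unfavorable, ds$pct_unfavorable))
  }
  cat("\n")
  top <- res[significant == TRUE][1:min(3, sum(res$significant))]
  if (nrow(top) && !anyNA(top$gene_id)) {
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %s: freq %s %.3f vs %s %.3f, p = %.3g (%s)\n",
                  top$gene_id[i], ref, top$freq_ref[i], der, top$freq_der[i],
                  top$p[i], top$direction[i]))
  }
  invisible(res)
}

run_scan("wild", "native", "domestication")
run_scan("native", "improved", "improvement")
cat("wrote results/scan_domestication.tsv and results/scan_improvement.tsv\n")
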