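#!/usr/bin/env Rscript
# Step 3 — pan-genome gene categories and per-individual gene counts.
#
# Presence frequencies over the whole retained cohort place each gene in
# one of four categories: core (100%), softcore (>99%, <100%), shell
# (1-99%) and cloud (<1%). Per-individual detected-gene counts are compared
# between population classes with a two-sided Mann-Whitney U test.

suppressPackageStartupMessages({
  library(pavkit)
  library(data.table)
})

m <- read_presence_matrix("results/presence_matrix.tsv")
popmap <- read_population_map("scratch/cohort/popmap.tsv")

fq <- presence_frequency(m)
cls <- classify_genes(fq)
smry <- category_summary(cls)
fwrite(cls, "results/gene_categories.tsv", sep = "\t")
fwrite(smry, "results/category_summary.tsv", sep = "\t")

cat(sprintf("pan-genome of %d genes (%d dispensable):\n",
            attr(smry, "total_genes"), attr(smry, "dispensable_genes")))
print(smry)

counts <- per_individual_gene_count(m)
counts_dt <- data.table(individual_id = names(counts), genes = counts)
counts_dt <- popmap[counts_dt, on = "individual_id"]
fwrite(counts_dt, "results/gene_counts_per_individual.tsv", sep = "\t")

cat("\nmean detected genes per class:\n")
print(counts_dt[, .(mean_genes = mean(genes), n = .N), by = class])

for (pair in list(c("wild", "native"), c("native", "improved"))) {
  a <- counts_dt[class == pair[1], genes]
  b <- counts_dt[class == pair[2], genes]
  mw <- mann_whitney_u(a, b)
  cat(sprintf("Mann-Whitney %s vs %s: U = %.1f, two-sided p = %.4g (%s)\n",
              pair[1], pair[2], mw$U, mw$p, mw$method))
}
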