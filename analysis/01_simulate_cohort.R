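#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Builds a desk-scale analogue of a resequenced goat cohort: 24 wild
# (Bezoar-like), 40 native and 20 improved individuals over 200 genes, with
# known ground-truth presence, gene models on a synthetic chromosome, and
# per-individual samtools-depth tracks (20x over present genes, 2% residual
# breadth over absent ones). Inputs for the later steps land in
# scratch/cohort/; nothing downstream ever looks at the ground truth except
# to audit the caller.

suppressPackageStartupMessages({
  library(pavkit)
  library(data.table)
})

dir.create("scratch/cohort/depth", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(
  n_genes = 200,
  n_individuals_per_population = c(wild = 24, native = 40, improved = 20),
  mean_depth = 20, absent_residual_breadth = 0.02,
  seed = 20240105)

models <- simulate_gene_models(cfg)
truth <- simulate_presence(cfg)
paths <- simulate_depth(truth, models, cfg, "scratch/cohort/depth")

write_bed12(models, "scratch/cohort/genes.bed")
write_population_map(truth$popmap, "scratch/cohort/popmap.tsv")
write_presence_matrix(truth$presence, "scratch/cohort/truth_matrix.tsv")
# The simulator emits depth over exons only, so the meaningful denominator
# for the genome-wide mean-depth filter is the total exonic length, not the
# chromosome span.
bodies <- select_gene_bodies(models)
exonic_total <- sum(unique(bodies, by = "gene_id")$exonic_length)
writeLines(as.character(exonic_total), "scratch/cohort/ref_length.txt")

cat(sprintf("simulated %d genes x %d individuals (%s)\n",
            nrow(truth$presence), ncol(truth$presence),
            paste(sprintf("%s=%d", names(cfg$n_individuals_per_population),
                          cfg$n_individuals_per_population), collapse = ", ")))
cat(sprintf("wrote %d depth tracks to scratch/cohort/depth/\n", length(paths)))
cat(sprintf("mean true presence frequency: %.3f\n", mean(truth$presence)))
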