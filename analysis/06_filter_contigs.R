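#!/usr/bin/env Rscript
# Step 6 — nonreference contig curation.
#
# Applies the map-to-pan curation cascade to a synthetic contig set with a
# known keep/drop oracle: retain contigs longer than 500 bp, exclude
# reference-redundant contigs (>= 90% identity and >= 80% coverage against
# the reference), then remove self-redundant contigs (>= 90% identity and
# >= 90% coverage against a longer surviving contig).

suppressPackageStartupMessages({
  library(pavkit)
  library(data.table)
})

x <- simulate_contigs_and_alignments(200, seed = 20240107)
Biostrings::writeXStringSet(x$contigs, "scratch/contigs.fa")
write_paf(x$ref_paf, "scratch/contigs_vs_ref.paf")
write_paf(x$self_paf, "scratch/contigs_vs_self.paf")

lens <- setNames(x$oracle$length, x$oracle$contig_id)
res <- filter_contigs(lens,
                      read_paf("scratch/contigs_vs_ref.paf"),
                      read_paf("scratch/contigs_vs_self.paf"))
fwrite(res$report, "results/contig_filter_report.tsv", sep = "\t")

cat(sprintf("retained %d / %d contigs\n", length(res$kept), nrow(res$report)))
print(res$report[, .N, by = drop_reason])
agree <- mean((res$report$contig_id %in% res$kept) ==
                (x$oracle$contig_id %in% x$oracle[keep == TRUE, contig_id]))
cat(sprintf("agreement with generator oracle: %.1f%%\n", 100 * agree))
cat("wrote results/contig_filter_report.tsv\n")
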