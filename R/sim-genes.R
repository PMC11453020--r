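#' Simulate gene models on a synthetic chromosome
#'
#' Lays out `n_genes` non-overlapping genes along one synthetic chromosome
#' (`chrS`). Every gene has at least one transcript; a subset gets a second,
#' strictly shorter transcript (one exon dropped, or a truncated exon for
#' single-exon genes) so longest-transcript selection is exercised with an
#' unambiguous oracle. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return a `pav_genes` exon table with attributes `chrom_length` (total
#'   synthetic reference length, used as the mean-depth denominator) and
#'   `longest_transcript` (named character vector, the per-gene oracle).
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    n <- config$n_genes
    rows <- vector("list", n)
    oracle <- character(n)
    cursor <- 1000L
    for (g in seq_len(n)) {
      gid <- sprintf("gene%04d", g)
      n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
      sizes <- sample(config$exon_length[1]:config$exon_length[2], n_ex,
                      replace = TRUE)
      introns <- if (n_ex > 1) sample(50:500, n_ex - 1L, replace = TRUE) else integer()
      starts <- cursor + cumsum(c(0L, sizes[-n_ex] + introns))
      ends <- starts + sizes
      strand <- sample(c("+", "-"), 1L)
      tx1 <- data.table(gene_id = gid, transcript_id = paste0(gid, ".t1"),
                        chrom = "chrS", strand = strand,
                        start = starts, end = ends)
      # every third gene gets a second, shorter isoform
      if (g %% 3L == 0L) {
        if (n_ex > 1) {
          drop <- sample(n_ex, 1L)
          tx2 <- tx1[-drop]
        } else {
          tx2 <- copy(tx1)
          tx2[, end := start + pmax(1L, (end - start) %/% 2L)]
        }
        tx2[, transcript_id := paste0(gid, ".t2")]
        rows[[g]] <- rbind(tx1, tx2)
      } else {
        rows[[g]] <- tx1
      }
      oracle[g] <- paste0(gid, ".t1")
      cursor <- max(ends) + sample(500:2000, 1L)
    }
    models <- validate_gene_models(rbindlist(rows))
    setattr(models, "chrom_length", as.integer(cursor + 1000L))
    setattr(models, "longest_transcript",
            setNames(oracle, sprintf("gene%04d", seq_len(n))))
    models
  })
}
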