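#' Simulate per-individual depth tracks from ground truth
#'
#' For genes present in an individual, every exonic base receives an
#' independent Poisson(`mean_depth`) read depth. For absent genes, a
#' contiguous block of `floor(absent_residual_breadth * exonic_length)`
#' bases at the start of the gene receives depth 2 — residual background
#' coverage placed contiguously as the simplest adversarial layout for a
#' breadth computation. Zero-depth positions are omitted from the files
#' (samtools-depth dialect). Intergenic positions are never emitted.
#'
#' @param truth a `pav_truth` from [simulate_presence()].
#' @param models gene models from [simulate_gene_models()].
#' @param config the same [sim_config()].
#' @param dir output directory; one `<individual_id>.depth.tsv` per
#'   individual. Created if missing.
#' @return named character vector of file paths, invisibly.
#' @export
simulate_depth <- function(truth, models, config, dir) {
  stopifnot(inherits(truth, "pav_truth"), inherits(config, "sim_config"))
  genes <- rownames(truth$presence)
  model_genes <- unique(models$gene_id)
  if (!setequal(genes, model_genes))
    stop("input error: gene ids differ between ground truth and gene models",
         call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  # exonic position union per gene (0-based half-open -> 1-based positions)
  ex <- as.data.table(models)[, {
    r <- IRanges::reduce(IRanges::IRanges(start + 1L, end))
    .(pos = unlist(Map(seq.int, IRanges::start(r), IRanges::end(r))),
      chrom = chrom[1])
  }, by = gene_id]
  setkey(ex, gene_id)
  exonic_len <- ex[, .N, by = gene_id]
  res_len <- setNames(
    as.integer(floor(config$absent_residual_breadth * exonic_len$N)),
    exonic_len$gene_id)

  ids <- colnames(truth$presence)
  paths <- setNames(file.path(dir, paste0(ids, ".depth.tsv")), ids)
  withr::with_seed(config$seed + 3L, {
    for (ind in ids) {
      present <- genes[truth$presence[, ind] == 1L]
      absent <- setdiff(genes, present)
      pres_dt <- ex[J(present)]
      pres_dt[, depth := rpois(.N, config$mean_depth)]
      abs_dt <- if (length(absent)) {
        ad <- ex[J(absent)][, head(.SD, res_len[[gene_id[1]]]), by = gene_id]
        if (nrow(ad)) ad[, depth := 2L]
        ad
      }
      track <- rbind(pres_dt[, .(chrom, pos, depth)],
                     if (!is.null(abs_dt) && nrow(abs_dt)) abs_dt[, .(chrom, pos, depth)])
      track <- track[depth > 0]
      setkey(track, chrom, pos)
      fwrite(track, paths[[ind]], sep = "\t", col.names = FALSE, quote = FALSE)
    }
  })
  invisible(paths)
}
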