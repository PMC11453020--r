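#' Caller configuration for presence/absence determination
#'
#' The SGSGeneloss-style rule: a gene is absent in an individual when bases
#' covered by at least `min_depth` reads make up less than
#' `absence_breadth_threshold` of the exon regions of its gene body
#' (the longest transcript); otherwise present. Individuals whose
#' genome-wide mean depth falls below `min_individual_mean_depth` are
#' excluded before calling.
#'
#' @param min_depth minimum per-base read depth counted as covered
#'   (default 2).
#' @param absence_breadth_threshold breadth below which a gene is called
#'   absent (default 0.05; the call is strict: breadth exactly at the
#'   threshold is present).
#' @param min_individual_mean_depth minimum genome-wide mean depth (x) for
#'   an individual to be retained (default 10).
#' @return a `caller_config` list.
#' @export
caller_config <- function(min_depth = 2L, absence_breadth_threshold = 0.05,
                          min_individual_mean_depth = 10) {
  if (min_depth < 1) stop_config("min_depth", "must be >= 1")
  if (absence_breadth_threshold <= 0 || absence_breadth_threshold >= 1)
    stop_config("absence_breadth_threshold", "must lie in (0, 1)")
  if (min_individual_mean_depth < 0)
    stop_config("min_individual_mean_depth", "must be >= 0")
  structure(list(min_depth = as.integer(min_depth),
                 absence_breadth_threshold = absence_breadth_threshold,
                 min_individual_mean_depth = min_individual_mean_depth),
            class = "caller_config")
}

#' Select each gene's body (longest transcript)
#'
#' For every gene, picks the transcript with the greatest exonic length
#' (sum of exon widths after unioning overlaps); ties are broken by the
#' lexicographically smallest transcript_id.
#'
#' @param models a gene-model exon table.
#' @return a `data.table` of body exons (gene_id, transcript_id, chrom,
#'   start, end) plus per-row `exonic_length` of the gene body.
#' @export
select_gene_bodies <- function(models) {
  ex <- as.data.table(models)
  if (nrow(ex) == 0)
    return(data.table(gene_id = character(), transcript_id = character(),
                      chrom = character(), start = integer(), end = integer(),
                      exonic_length = integer()))
  lens <- ex[, {
    r <- IRanges::reduce(IRanges::IRanges(start + 1L, end))
    .(exonic_length = sum(IRanges::width(r)))
  }, by = .(gene_id, transcript_id)]
  setorder(lens, gene_id, -exonic_length, transcript_id)
  chosen <- lens[, .SD[1], by = gene_id]
  body <- ex[chosen[, .(gene_id, transcript_id)],
             on = c("gene_id", "transcript_id")]
  body <- body[chosen[, .(gene_id, transcript_id, exonic_length)],
               on = c("gene_id", "transcript_id")]
  setorder(body, gene_id, start)
  body[, .(gene_id, transcript_id, chrom, start, end, exonic_length)]
}

#' Filter individuals by genome-wide mean sequencing depth
#'
#' Mean depth is the sum of all listed per-base depths divided by the total
#' reference length (not only covered positions), matching the usual
#' meaning of "average sequencing depth". Individuals are retained when the
#' mean is at or above the threshold.
#'
#' @param tracks named list of depth tracks (see [read_depth()]).
#' @param ref_length total reference length in bp (the denominator).
#' @param config a [caller_config()].
#' @return character vector of retained individual ids.
#' @export
filter_individuals_by_depth <- function(tracks, ref_length,
                                        config = caller_config()) {
  if (missing(ref_length) || is.null(ref_length) || is.na(ref_length) ||
      ref_length <= 0)
    stop_config("ref_length", "must be a positive total reference length")
  means <- vapply(tracks, function(tr) sum(as.numeric(tr$depth)) / ref_length,
                  numeric(1))
  names(tracks)[means >= config$min_individual_mean_depth]
}

#' Breadth of coverage over a gene body's exons
#'
#' Fraction of exonic bases (after unioning exons) covered at depth >=
#' `min_depth`. Positions missing from the track count as depth 0.
#'
#' @param track a depth track.
#' @param bodies gene bodies from [select_gene_bodies()] (one or many
#'   genes).
#' @param min_depth minimum depth for a base to count as covered.
#' @return `data.table` (gene_id, exonic_length, covered, breadth).
#' @export
exon_breadth <- function(track, bodies, min_depth = 2L) {
  bodies <- as.data.table(bodies)
  pos_dt <- bodies[, {
    r <- IRanges::reduce(IRanges::IRanges(start + 1L, end))
    .(pos = unlist(Map(seq.int, IRanges::start(r), IRanges::end(r))),
      chrom = chrom[1])
  }, by = gene_id]
  hit <- track[pos_dt, on = c("chrom", "pos")]
  hit[is.na(depth), depth := 0L]
  res <- hit[, .(exonic_length = .N, covered = sum(depth >= min_depth)),
             by = gene_id]
  res[, breadth := covered / exonic_length]
  res[bodies[, .(gene_id = unique(gene_id))], on = "gene_id"]
}

#' Presence call from coverage breadth
#'
#' Absent iff breadth is strictly below the absence threshold; a breadth
#' exactly at the threshold is called present ("less than" rule).
#'
#' @param breadth numeric breadth(s) in `[0, 1]`.
#' @param config a [caller_config()].
#' @return character vector, `"present"` or `"absent"`.
#' @export
call_presence <- function(breadth, config = caller_config()) {
  stopifnot(all(breadth >= 0 & breadth <= 1))
  ifelse(breadth < config$absence_breadth_threshold, "absent", "present")
}

#' Build the genes x individuals presence matrix
#'
#' Applies [exon_breadth()] and [call_presence()] per gene and individual.
#' Only pre-filtered (retained) individuals should be passed; an individual
#' named in `individuals` but missing from `tracks` is a hard error —
#' presence is never imputed.
#'
#' @param tracks named list of depth tracks.
#' @param bodies gene bodies from [select_gene_bodies()].
#' @param config a [caller_config()].
#' @param individuals individuals to call; defaults to all of `tracks`.
#' @return integer 0/1 matrix (genes x individuals); 1 = present.
#' @export
build_presence_matrix <- function(tracks, bodies, config = caller_config(),
                                  individuals = names(tracks)) {
  missing_ids <- setdiff(individuals, names(tracks))
  if (length(missing_ids))
    stop(sprintf("no depth track for individual '%s'", missing_ids[1]),
         call. = FALSE)
  genes <- unique(as.data.table(bodies)$gene_id)
  if (length(individuals) == 0) {
    warning("no retained individuals; presence matrix is empty")
    return(matrix(integer(), nrow = length(genes), ncol = 0,
                  dimnames = list(genes, character())))
  }
  m <- matrix(0L, nrow = length(genes), ncol = length(individuals),
              dimnames = list(genes, individuals))
  for (ind in individuals) {
    br <- exon_breadth(tracks[[ind]], bodies, config$min_depth)
    calls <- call_presence(br$breadth, config)
    m[br$gene_id, ind] <- as.integer(calls == "present")
  }
  m
}
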