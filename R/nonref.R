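#' Length filter for nonreference contigs
#'
#' Contigs are retained only when strictly longer than the threshold
#' ("exceeding 500 bp"): a 500-bp contig is dropped, a 501-bp contig kept.
#'
#' @param lengths named integer vector, contig_id -> length in bp.
#' @param min_exclusive exclusive minimum length (default 500).
#' @return character vector of retained contig ids.
#' @export
filter_by_length <- function(lengths, min_exclusive = 500L) {
  names(lengths)[lengths > min_exclusive]
}

#' Summarize PAF alignments per contig (or per contig pair)
#'
#' Coverage is the fraction of the query contig inside the union of its
#' aligned query intervals; identity is the block-length-weighted mean of
#' per-alignment matches/block_len (equivalently total matches over total
#' block length). Both definitions are deterministic and order-independent.
#' A contig with no alignments has coverage 0 and identity 0.
#'
#' @param paf PAF records (see [read_paf()]).
#' @param by `"query"` (one summary per query contig) or `"pair"` (one per
#'   query-target pair, used by the self-redundancy filter; trivial
#'   self-hits query == target are ignored).
#' @return `data.table` (query_id \[, target_id\], query_len, coverage,
#'   identity).
#' @export
summarize_alignments <- function(paf, by = c("query", "pair")) {
  by <- match.arg(by)
  paf <- validate_paf(paf)
  if (by == "pair") paf <- paf[query_id != target_id]
  keys <- if (by == "query") "query_id" else c("query_id", "target_id")
  if (nrow(paf) == 0) {
    empty <- data.table(query_id = character(), query_len = integer(),
                        coverage = numeric(), identity = numeric())
    if (by == "pair") empty[, target_id := character()]
    return(empty)
  }
  paf[, {
    r <- IRanges::reduce(IRanges::IRanges(query_start + 1L, query_end))
    .(query_len = query_len[1],
      coverage = sum(IRanges::width(r)) / query_len[1],
      identity = sum(matches) / sum(block_len))
  }, by = keys]
}

#' Reference-redundancy filter
#'
#' A contig is excluded when its reference-alignment summary satisfies
#' identity >= `min_identity` AND coverage >= `min_coverage` (both
#' boundaries inclusive).
#'
#' @param summaries per-query summaries from [summarize_alignments()]
#'   against the reference.
#' @param min_identity,min_coverage inclusive thresholds (defaults 0.90 and
#'   0.80).
#' @return character vector of excluded contig ids.
#' @export
filter_reference_redundant <- function(summaries, min_identity = 0.90,
                                       min_coverage = 0.80) {
  s <- as.data.table(summaries)
  s[identity >= min_identity & coverage >= min_coverage, query_id]
}

#' Self-redundancy filter
#'
#' Contigs are compared pairwise through self-alignment records (trivial
#' query == target hits ignored). A record's coverage and identity describe
#' its query, so a qualifying pair (identity >= `min_identity`, query
#' coverage >= `min_coverage`) removes the query when the query is the
#' shorter contig — or, at equal length, the lexicographically larger id.
#' Contigs are processed in decreasing length order (ties: lexicographically
#' smaller first), and a contig can only be removed by a partner that
#' itself survives, so cascades resolve deterministically.
#'
#' @param self_paf self-alignment PAF records among the candidate contigs.
#' @param lengths named integer vector, contig_id -> length, for every
#'   candidate contig (including contigs without self hits).
#' @param min_identity,min_coverage inclusive thresholds (defaults 0.90 and
#'   0.90).
#' @return character vector of excluded contig ids.
#' @export
filter_self_redundant <- function(self_paf, lengths, min_identity = 0.90,
                                  min_coverage = 0.90) {
  pairs <- summarize_alignments(self_paf, by = "pair")
  pairs <- pairs[identity >= min_identity & coverage >= min_coverage]
  pairs <- pairs[query_id %in% names(lengths) & target_id %in% names(lengths)]
  # the query must be the removal candidate: shorter, or equal and lex-larger
  pairs <- pairs[lengths[query_id] < lengths[target_id] |
                 (lengths[query_id] == lengths[target_id] &
                  query_id > target_id)]
  ids <- names(lengths)
  ord <- ids[order(-as.numeric(lengths), ids)]  # length desc, ties id asc
  kept <- character(0)
  removed <- character(0)
  for (ctg in ord) {
    hits <- pairs[query_id == ctg, target_id]
    if (length(hits) && any(hits %in% kept)) {
      removed <- c(removed, ctg)
    } else {
      kept <- c(kept, ctg)
    }
  }
  removed
}

#' Apply the full nonreference-contig curation cascade
#'
#' Order matches the map-to-pan recipe: optional pre-made exclusion list,
#' then length (> 500 bp retained), then reference redundancy (>= 90%
#' identity and >= 80% coverage excluded), then self redundancy (>= 90%
#' identity and >= 90% coverage, shorter contig removed). Each filter only
#' sees the survivors of the previous one. Every filter is idempotent.
#'
#' @param lengths named integer vector of contig lengths.
#' @param ref_paf alignments of contigs against the reference.
#' @param self_paf self-alignments among contigs.
#' @param exclude_list optional contig ids to drop first (e.g. an external
#'   contamination screen).
#' @param min_length exclusive length threshold.
#' @param ref_identity,ref_coverage reference-redundancy thresholds.
#' @param self_identity,self_coverage self-redundancy thresholds.
#' @return list with `kept` (character vector) and `report` (`data.table`
#'   contig_id, length, keep, drop_reason).
#' @export
filter_contigs <- function(lengths, ref_paf = NULL, self_paf = NULL,
                           exclude_list = NULL, min_length = 500L,
                           ref_identity = 0.90, ref_coverage = 0.80,
                           self_identity = 0.90, self_coverage = 0.90) {
  report <- data.table(contig_id = names(lengths),
                       length = as.integer(lengths),
                       keep = TRUE, drop_reason = NA_character_)
  setkey(report, contig_id)
  if (length(exclude_list))
    report[J(intersect(exclude_list, report$contig_id)),
           `:=`(keep = FALSE, drop_reason = "excluded")]

  survivors <- report[keep == TRUE, contig_id]
  short <- setdiff(survivors, filter_by_length(lengths[survivors], min_length))
  report[J(short), `:=`(keep = FALSE, drop_reason = "short")]

  survivors <- report[keep == TRUE, contig_id]
  if (!is.null(ref_paf) && nrow(ref_paf)) {
    s <- summarize_alignments(ref_paf[query_id %in% survivors], by = "query")
    drop <- filter_reference_redundant(s, ref_identity, ref_coverage)
    report[J(drop), `:=`(keep = FALSE, drop_reason = "reference_redundant")]
  }

  survivors <- report[keep == TRUE, contig_id]
  if (!is.null(self_paf) && nrow(self_paf)) {
    sp <- self_paf[query_id %in% survivors & target_id %in% survivors]
    drop <- filter_self_redundant(sp, lengths[survivors],
                                  self_identity, self_coverage)
    report[J(drop), `:=`(keep = FALSE, drop_reason = "self_redundant")]
  }

  list(kept = report[keep == TRUE, contig_id], report = report[])
}
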