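#' Read PAF alignment records
#'
#' Parses the 12 mandatory PAF columns. Query coordinates are 0-based
#' half-open, as in the format. Per-record invariants (coordinates within
#' the declared query length, matches <= block length) are enforced.
#'
#' @param path PAF file path.
#' @return a `data.table` with columns query_id, query_len, query_start,
#'   query_end, strand, target_id, target_len, target_start, target_end,
#'   matches, block_len, mapq.
#' @export
read_paf <- function(path) {
  cols <- c("query_id", "query_len", "query_start", "query_end", "strand",
            "target_id", "target_len", "target_start", "target_end",
            "matches", "block_len", "mapq")
  paf <- fread(path, sep = "\t", header = FALSE, fill = TRUE)
  if (nrow(paf) == 0)
    return(setNames(data.table(character(), integer(), integer(), integer(),
                               character(), character(), integer(), integer(),
                               integer(), integer(), integer(), integer()),
                    cols))
  if (ncol(paf) < 12)
    stop("parse error: PAF requires 12 mandatory columns", call. = FALSE)
  paf <- paf[, 1:12]
  setnames(paf, cols)
  int_cols <- setdiff(cols, c("query_id", "strand", "target_id"))
  paf[, (int_cols) := lapply(.SD, as.integer), .SDcols = int_cols]
  validate_paf(paf)
}

validate_paf <- function(paf) {
  paf <- as.data.table(paf)
  if (nrow(paf)) {
    if (any(paf$query_start < 0 | paf$query_start >= paf$query_end))
      stop("input error: PAF query interval with start >= end or negative start",
           call. = FALSE)
    if (any(paf$query_end > paf$query_len))
      stop("input error: PAF query interval exceeds declared query length",
           call. = FALSE)
    if (any(paf$matches > paf$block_len))
      stop("input error: PAF matches exceed block length", call. = FALSE)
    incons <- paf[, uniqueN(query_len), by = query_id][V1 > 1]
    if (nrow(incons))
      stop(sprintf("input error: inconsistent query_len for contig '%s'",
                   incons$query_id[1]), call. = FALSE)
  }
  paf
}

#' Write PAF alignment records
#'
#' @param paf data.table as produced by [read_paf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  fwrite(as.data.table(paf), path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
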