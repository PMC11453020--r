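#' Read gene models from BED12 or GFF3
#'
#' Parses gene models into the package's exon table: one row per exon with
#' columns `gene_id`, `transcript_id`, `chrom`, `strand`, `start`, `end`.
#' Internal coordinates are 0-based half-open everywhere; GFF3's 1-based
#' closed exon coordinates are converted at this boundary. Rows are ordered
#' by (chrom, gene start, gene_id) with exons sorted within transcripts.
#'
#' BED12 carries one transcript per line; the name field is interpreted as
#' `gene_id:transcript_id`, or as both ids when it contains no colon.
#' For GFF3, `gene`, `mRNA`/`transcript` and `exon` features are consumed
#' and linked through `ID`/`Parent` attributes.
#'
#' @param path file path.
#' @param format `"bed12"` or `"gff3"`.
#' @return a `data.table` exon table (class `pav_genes`).
#' @export
read_gene_models <- function(path, format = c("bed12", "gff3")) {
  format <- match.arg(format)
  lines <- readLines(path)
  exons <- switch(format,
    bed12 = parse_bed12(lines),
    gff3 = parse_gff3(lines))
  validate_gene_models(exons)
}

parse_error <- function(line_no, msg) {
  stop(sprintf("parse error at line %d: %s", line_no, msg), call. = FALSE)
}

parse_bed12 <- function(lines) {
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12)
      parse_error(i, sprintf("expected 12 BED fields, found %d", length(f)))
    chrom_start <- suppressWarnings(as.integer(f[2]))
    n_blocks <- suppressWarnings(as.integer(f[10]))
    if (is.na(chrom_start) || is.na(n_blocks))
      parse_error(i, "non-integer chromStart or blockCount")
    sizes <- suppressWarnings(as.integer(strsplit(f[11], ",")[[1]]))
    starts <- suppressWarnings(as.integer(strsplit(f[12], ",")[[1]]))
    if (anyNA(sizes) || anyNA(starts) ||
        length(sizes) != n_blocks || length(starts) != n_blocks)
      parse_error(i, "blockSizes/blockStarts do not match blockCount")
    ids <- strsplit(f[4], ":", fixed = TRUE)[[1]]
    gene <- ids[1]
    tx <- if (length(ids) >= 2) ids[2] else ids[1]
    j <- j + 1L
    out[[j]] <- data.table(
      gene_id = gene, transcript_id = tx, chrom = f[1],
      strand = if (f[6] %in% c("+", "-")) f[6] else ".",
      start = chrom_start + starts,
      end = chrom_start + starts + sizes)
  }
  rbindlist(out)
}

parse_gff3 <- function(lines) {
  is_data <- !grepl("^#", lines) & nzchar(lines)
  genes <- character()            # ID -> ID (known gene features)
  tx_parent <- character()        # transcript ID -> gene ID
  exon_rows <- vector("list", 0L)
  for (i in which(is_data)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9)
      parse_error(i, sprintf("expected 9 GFF3 columns, found %d", length(f)))
    type <- f[3]
    if (!type %in% c("gene", "mRNA", "transcript", "exon")) next
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1) || start1 > end1)
      parse_error(i, "invalid start/end coordinates")
    attrs <- gff3_attrs(f[9])
    if (type == "gene") {
      if (is.null(attrs[["ID"]])) parse_error(i, "gene feature without ID")
      genes[attrs[["ID"]]] <- attrs[["ID"]]
    } else if (type %in% c("mRNA", "transcript")) {
      id <- attrs[["ID"]]; parent <- attrs[["Parent"]]
      if (is.null(id) || is.null(parent))
        parse_error(i, sprintf("%s feature without ID/Parent", type))
      if (id %in% names(tx_parent))
        stop(sprintf("structural error: duplicate transcript_id '%s'", id),
             call. = FALSE)
      tx_parent[id] <- parent
    } else { # exon
      parent <- attrs[["Parent"]]
      if (is.null(parent)) parse_error(i, "exon without Parent")
      exon_rows[[length(exon_rows) + 1L]] <- data.table(
        transcript_id = parent, chrom = f[1],
        strand = if (f[7] %in% c("+", "-")) f[7] else ".",
        start = start1 - 1L, end = end1, line = i)
    }
  }
  ex <- rbindlist(exon_rows)
  if (nrow(ex) == 0)
    return(data.table(gene_id = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer()))
  orphan_tx <- setdiff(unique(ex$transcript_id), names(tx_parent))
  if (length(orphan_tx))
    stop(sprintf("structural error: exon(s) reference unknown transcript '%s'",
                 orphan_tx[1]), call. = FALSE)
  orphan_gene <- setdiff(unname(tx_parent), names(genes))
  if (length(orphan_gene))
    stop(sprintf("structural error: transcript without parent gene '%s'",
                 orphan_gene[1]), call. = FALSE)
  ex[, gene_id := tx_parent[transcript_id]]
  ex[, line := NULL]
  setcolorder(ex, c("gene_id", "transcript_id", "chrom", "strand", "start", "end"))
  ex
}

gff3_attrs <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) x[2])
  names(vals) <- vapply(kv, `[`, "", 1)
  vals
}

#' Validate and order a gene-model exon table
#'
#' Enforces the exon-table invariants: positive half-open intervals, sorted
#' non-overlapping exons within each transcript, and at least one transcript
#' per gene; then applies the canonical (chrom, gene start, gene_id)
#' ordering.
#'
#' @param exons a data.table with columns gene_id, transcript_id, chrom,
#'   strand, start, end (0-based half-open).
#' @return the validated table, keyed and classed `pav_genes`.
#' @export
validate_gene_models <- function(exons) {
  exons <- as.data.table(exons)
  if (nrow(exons) > 0) {
    if (any(exons$start >= exons$end))
      stop("invalid gene model: exon with start >= end", call. = FALSE)
    if (any(exons$start < 0))
      stop("invalid gene model: negative coordinate", call. = FALSE)
    setorder(exons, gene_id, transcript_id, start)
    overlaps <- exons[, any(head(end, -1) > tail(start, -1)),
                      by = .(gene_id, transcript_id)]$V1
    if (any(overlaps))
      stop("invalid gene model: overlapping exons within a transcript",
           call. = FALSE)
    # one chromosome per gene
    multi <- exons[, uniqueN(chrom), by = gene_id][V1 > 1]
    if (nrow(multi))
      stop(sprintf("invalid gene model: gene '%s' spans multiple chromosomes",
                   multi$gene_id[1]), call. = FALSE)
    gene_pos <- exons[, .(gstart = min(start), gchrom = chrom[1]), by = gene_id]
    setorder(gene_pos, gchrom, gstart, gene_id)
    exons <- exons[J(gene_pos$gene_id), on = "gene_id"]
  }
  setattr(exons, "class", unique(c("pav_genes", class(exons))))
  exons
}

#' Write gene models as BED12
#'
#' One line per transcript; the name field is `gene_id:transcript_id`.
#'
#' @param exons a gene-model exon table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(exons, path) {
  exons <- as.data.table(exons)
  if (nrow(exons) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  setorder(exons, gene_id, transcript_id, start)
  bed <- exons[, {
    cs <- min(start)
    .(chrom = chrom[1], chromStart = cs, chromEnd = max(end),
      name = paste0(gene_id, ":", transcript_id),
      score = 0L, strand = strand[1], thickStart = cs, thickEnd = max(end),
      itemRgb = "0", blockCount = .N,
      blockSizes = paste0(paste(end - start, collapse = ","), ","),
      blockStarts = paste0(paste(start - cs, collapse = ","), ","))
  }, by = .(gene_id, transcript_id)]
  gene_pos <- bed[, .(gstart = min(chromStart), gchrom = chrom[1]), by = gene_id]
  setorder(gene_pos, gchrom, gstart, gene_id)
  bed <- bed[J(gene_pos$gene_id), on = "gene_id"]
  fwrite(bed[, !c("gene_id", "transcript_id")], path, sep = "\t",
         col.names = FALSE, quote = FALSE)
  invisible(path)
}
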