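#' Read a samtools-depth style per-base depth track
#'
#' Three tab-separated columns: chromosome, 1-based position, read depth.
#' Positions absent from the file mean depth 0 (the samtools-depth default
#' dialect omits zero-depth positions); [depth_at()] honours that.
#'
#' @param path file path.
#' @param individual_id identifier attached to the track; defaults to the
#'   file name stripped of extensions.
#' @return a `data.table` (chrom, pos, depth) with attribute
#'   `individual_id`.
#' @export
read_depth <- function(path, individual_id = NULL) {
  individual_id <- individual_id %||% sub("\\..*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    track <- data.table(chrom = character(), pos = integer(), depth = integer())
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad_len <- which(lengths(parts) != 3)
    if (length(bad_len))
      stop(sprintf("parse error at line %d: expected 3 columns", bad_len[1]),
           call. = FALSE)
    m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
    pos <- suppressWarnings(as.integer(m[, 2]))
    dep <- suppressWarnings(as.integer(m[, 3]))
    bad <- which(is.na(pos) | is.na(dep) | pos < 1 | dep < 0 |
                 m[, 2] != as.character(pos) | m[, 3] != as.character(dep))
    if (length(bad))
      stop(sprintf("parse error at line %d: non-integer or negative pos/depth",
                   bad[1]), call. = FALSE)
    track <- data.table(chrom = m[, 1], pos = pos, depth = dep)
  }
  setkey(track, chrom, pos)
  setattr(track, "individual_id", individual_id)
  track
}

#' Depth lookup with zero default
#'
#' @param track a depth track from [read_depth()].
#' @param chrom chromosome name.
#' @param positions 1-based positions.
#' @return integer depths; unlisted positions return 0.
#' @export
depth_at <- function(track, chrom, positions) {
  lookup <- data.table(chrom = chrom, pos = as.integer(positions))
  hit <- track[lookup, on = c("chrom", "pos")]
  fifelse(is.na(hit$depth), 0L, hit$depth)
}

#' Write a depth track as samtools-depth TSV
#'
#' Zero-depth rows are dropped, matching the dialect [read_depth()] expects.
#'
#' @param track data.table (chrom, pos, depth).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth <- function(track, path) {
  fwrite(as.data.table(track)[depth > 0], path, sep = "\t",
         col.names = FALSE, quote = FALSE)
  invisible(path)
}
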