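#' Write / read a presence/absence matrix
#'
#' TSV with gene ids in the first column (`gene_id`) and one 0/1 column per
#' individual. The writer/reader pair round-trips losslessly.
#'
#' @param m integer or logical matrix, genes in rows (rownames = gene ids),
#'   individuals in columns (colnames = individual ids).
#' @param path file path.
#' @return `write_presence_matrix`: `path` invisibly;
#'   `read_presence_matrix`: an integer 0/1 matrix.
#' @export
write_presence_matrix <- function(m, path) {
  m <- presence_as_matrix(m)
  rn <- rownames(m) %||% character(0)
  dt <- cbind(data.frame(gene_id = rn, stringsAsFactors = FALSE),
              as.data.frame(m, row.names = FALSE))
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = list(character = 1))
  if (nrow(dt) == 0) {
    m <- matrix(integer(), nrow = 0, ncol = ncol(dt) - 1,
                dimnames = list(NULL, setdiff(names(dt), "gene_id")))
    return(m)
  }
  genes <- dt[[1]]
  if (ncol(dt) == 1) {
    return(matrix(integer(), nrow = length(genes), ncol = 0,
                  dimnames = list(genes, character())))
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  if (anyNA(m) || any(m != 0L & m != 1L))
    stop("parse error: presence matrix cells must be 0 or 1", call. = FALSE)
  rownames(m) <- genes
  m
}

presence_as_matrix <- function(m) {
  if (is.logical(m)) storage.mode(m) <- "integer"
  if (!is.matrix(m) || !all(m %in% c(0L, 1L)))
    stop("presence matrix must be a 0/1 (or logical) matrix", call. = FALSE)
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("gene%04d", seq_len(nrow(m)))
  m
}

#' Read / write a population map
#'
#' TSV with header `individual_id`, `population`, `class`; class is one of
#' wild, native, improved. Every individual appears exactly once.
#'
#' @param popmap data.table/data.frame with those three columns.
#' @param path file path.
#' @return `read_population_map`: a keyed `data.table`.
#' @export
read_population_map <- function(path) {
  pm <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  validate_population_map(pm)
}

#' @rdname read_population_map
#' @export
write_population_map <- function(popmap, path) {
  fwrite(validate_population_map(popmap), path, sep = "\t", quote = FALSE)
  invisible(path)
}

validate_population_map <- function(popmap) {
  pm <- as.data.table(popmap)
  need <- c("individual_id", "population", "class")
  if (!all(need %in% names(pm)))
    stop("population map needs columns individual_id, population, class",
         call. = FALSE)
  pm <- pm[, ..need]
  if (anyDuplicated(pm$individual_id))
    stop("population map: individual appears more than once", call. = FALSE)
  bad <- setdiff(unique(pm$class), c("wild", "native", "improved"))
  if (length(bad))
    stop(sprintf("population map: unknown class '%s'", bad[1]), call. = FALSE)
  setkey(pm, individual_id)
  pm
}
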