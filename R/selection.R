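#' Two-sided Fisher's exact test for a 2x2 presence table
#'
#' The table is (present, absent) in population A versus population B. The
#' two-sided p-value follows the probability-mass convention: the sum of
#' hypergeometric probabilities of all tables with the same margins whose
#' point probability does not exceed that of the observed table.
#'
#' @param a present in A; @param b absent in A;
#' @param c_ present in B; @param d absent in B.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b, c_, d) {
  counts <- c(a, b, c_, d)
  if (any(counts < 0)) stop("negative count in contingency table", call. = FALSE)
  if (sum(counts) == 0) stop("all-zero contingency table", call. = FALSE)
  fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' Scan configuration for the presence-frequency selection test
#'
#' @param reference_population population treated as ancestral/source
#'   (e.g. Bezoar for domestication, native goats for improvement).
#' @param derived_population the domesticated/improved population.
#' @param alpha significance threshold on the raw two-sided p
#'   (default 0.005; no multiple-testing correction, matching the raw-P
#'   convention — a Benjamini-Hochberg q column is still reported).
#' @return a `scan_config` list.
#' @export
scan_config <- function(reference_population, derived_population,
                        alpha = 0.005) {
  if (alpha <= 0 || alpha >= 1) stop_config("alpha", "must lie in (0, 1)")
  structure(list(reference_population = reference_population,
                 derived_population = derived_population,
                 alpha = alpha), class = "scan_config")
}

#' Per-gene selection scan between two populations
#'
#' For every gene, builds the 2x2 presence/absence table between the
#' reference and derived populations, computes the two-sided Fisher exact
#' p, and labels significant genes (p < alpha) as favorable (derived
#' frequency higher than reference) or unfavorable (lower). Equal
#' frequencies yield direction "none". Records are sorted by p ascending,
#' ties by gene_id.
#'
#' @param m presence matrix.
#' @param popmap population map.
#' @param config a [scan_config()].
#' @return `data.table` with columns gene_id, n_present_ref, n_ref,
#'   n_present_der, n_der, freq_ref, freq_der, p, q_bh, significant,
#'   direction.
#' @export
scan_selection <- function(m, popmap, config) {
  m <- presence_as_matrix(m)
  pm <- validate_population_map(popmap)
  ref_ids <- intersect(colnames(m),
                       pm[population == config$reference_population, individual_id])
  der_ids <- intersect(colnames(m),
                       pm[population == config$derived_population, individual_id])
  if (length(ref_ids) == 0)
    stop(sprintf("population '%s' has no individuals in the matrix",
                 config$reference_population), call. = FALSE)
  if (length(der_ids) == 0)
    stop(sprintf("population '%s' has no individuals in the matrix",
                 config$derived_population), call. = FALSE)
  n_ref <- length(ref_ids); n_der <- length(der_ids)
  pres_ref <- as.integer(rowSums(m[, ref_ids, drop = FALSE]))
  pres_der <- as.integer(rowSums(m[, der_ids, drop = FALSE]))
  p <- vapply(seq_len(nrow(m)), function(i)
    fisher_exact_two_sided(pres_ref[i], n_ref - pres_ref[i],
                           pres_der[i], n_der - pres_der[i]),
    numeric(1))
  out <- data.table(
    gene_id = rownames(m),
    n_present_ref = pres_ref, n_ref = n_ref,
    n_present_der = pres_der, n_der = n_der,
    freq_ref = pres_ref / n_ref, freq_der = pres_der / n_der,
    p = p, q_bh = p.adjust(p, method = "BH"))
  out[, significant := p < config$alpha]
  out[, direction := fifelse(!significant | freq_der == freq_ref, "none",
                     fifelse(freq_der > freq_ref, "favorable", "unfavorable"))]
  setorder(out, p, gene_id)
  out[]
}

#' Summarize favorable/unfavorable directions among significant genes
#'
#' Percentages are computed on the significant total and rounded half-up to
#' two decimals.
#'
#' @param records scan results from [scan_selection()], or a named
#'   vector/list with elements `favorable` and `unfavorable`.
#' @return list with n_significant, n_favorable, n_unfavorable,
#'   pct_favorable, pct_unfavorable.
#' @export
direction_summary <- function(records) {
  if (is.data.frame(records)) {
    rec <- as.data.table(records)
    fav <- rec[significant == TRUE & direction == "favorable", .N]
    unf <- rec[significant == TRUE & direction == "unfavorable", .N]
  } else {
    fav <- as.integer(records[["favorable"]])
    unf <- as.integer(records[["unfavorable"]])
  }
  tot <- fav + unf
  list(n_significant = tot, n_favorable = fav, n_unfavorable = unf,
       pct_favorable = if (tot) percent(fav / tot) else NA_real_,
       pct_unfavorable = if (tot) percent(unf / tot) else NA_real_)
}
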