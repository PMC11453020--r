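#' Per-gene presence frequency
#'
#' Exact rational frequencies (n_present / n_total) over a cohort or a
#' subset of individuals; display rounding is left to [percent()].
#'
#' @param m presence matrix (genes x individuals, 0/1).
#' @param individuals optional subset of column names; default all.
#' @return `data.table` (gene_id, n_present, n_total, frequency).
#' @export
presence_frequency <- function(m, individuals = NULL) {
  m <- presence_as_matrix(m)
  if (!is.null(individuals)) {
    missing_ids <- setdiff(individuals, colnames(m))
    if (length(missing_ids))
      stop(sprintf("unknown individual '%s'", missing_ids[1]), call. = FALSE)
    m <- m[, individuals, drop = FALSE]
  }
  if (ncol(m) == 0) stop("presence frequency over an empty individual set",
                         call. = FALSE)
  data.table(gene_id = rownames(m),
             n_present = as.integer(rowSums(m)),
             n_total = ncol(m))[, frequency := n_present / n_total][]
}

#' Classify genes into pan-genome categories
#'
#' Core: present in all individuals (frequency exactly 1). Softcore:
#' frequency in (0.99, 1). Shell: frequency in \[0.01, 0.99\] (both ends
#' inclusive, so the four categories partition \[0, 1\]). Cloud: frequency
#' below 0.01. Genes present in no retained individual are cloud and
#' flagged in the `zero_presence` column for inspection.
#'
#' @param freq frequency table from [presence_frequency()].
#' @return `data.table` (gene_id, n_present, n_total, frequency, category,
#'   zero_presence); `category` is a factor with levels core, softcore,
#'   shell, cloud.
#' @export
classify_genes <- function(freq) {
  freq <- as.data.table(freq)
  out <- copy(freq)
  out[, category := fifelse(n_present == n_total, "core",
                    fifelse(frequency > 0.99, "softcore",
                    fifelse(frequency < 0.01, "cloud", "shell")))]
  out[, category := factor(category, levels = c("core", "softcore", "shell", "cloud"))]
  out[, zero_presence := n_present == 0L]
  out[]
}

#' Summarize pan-genome category counts and percentages
#'
#' Percentages are computed on the total gene count and rounded half-up to
#' two decimals. The dispensable total (softcore + shell + cloud) is
#' attached as an attribute and printed.
#'
#' @param assignment either a classification table from [classify_genes()]
#'   or a named vector/list of category counts
#'   (core/softcore/shell/cloud).
#' @return `data.table` (category, n, pct) with attributes `total_genes`
#'   and `dispensable_genes`.
#' @export
category_summary <- function(assignment) {
  levels <- c("core", "softcore", "shell", "cloud")
  if (is.data.frame(assignment)) {
    counts <- table(factor(as.data.table(assignment)$category, levels = levels))
    counts <- setNames(as.integer(counts), levels)
  } else {
    if (!all(levels %in% names(assignment)))
      stop("category counts must name core, softcore, shell and cloud",
           call. = FALSE)
    counts <- setNames(as.integer(assignment[levels]), levels)
  }
  total <- sum(counts)
  out <- data.table(category = factor(levels, levels = levels),
                    n = counts,
                    pct = percent(counts / total))
  setattr(out, "total_genes", total)
  setattr(out, "dispensable_genes", total - counts[["core"]])
  out
}

#' Per-individual detected-gene counts
#'
#' Number of genes called present in each individual, optionally restricted
#' to individuals of one population class.
#'
#' @param m presence matrix.
#' @param popmap population map (required when `class_filter` is given).
#' @param class_filter optional class in wild/native/improved.
#' @return named integer vector, individual -> gene count.
#' @export
per_individual_gene_count <- function(m, popmap = NULL, class_filter = NULL) {
  m <- presence_as_matrix(m)
  if (!is.null(class_filter)) {
    if (!class_filter %in% c("wild", "native", "improved"))
      stop(sprintf("unknown class label '%s'", class_filter), call. = FALSE)
    if (is.null(popmap)) stop("class_filter requires a population map",
                              call. = FALSE)
    pm <- validate_population_map(popmap)
    keep_ids <- intersect(colnames(m), pm[class == class_filter, individual_id])
    m <- m[, keep_ids, drop = FALSE]
  }
  setNames(as.integer(colSums(m)), colnames(m))
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed for the first sample (rank-sum minus its minimum). The
#' two-sided p-value comes from the exact null distribution of U when
#' `n_a * n_b <= 400` and there are no ties; otherwise from the normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b numeric samples (both non-empty).
#' @return list with `U`, `p`, and `method` ("exact" or "approximate").
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && n_a * n_b <= 400) {
    if (u > n_a * n_b / 2) {
      p <- 1 - pwilcox(u - 1, n_a, n_b)
    } else {
      p <- pwilcox(u, n_a, n_b)
    }
    p <- min(2 * p, 1)
    list(U = u, p = p, method = "exact")
  } else {
    wt <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                  correct = TRUE))
    list(U = u, p = wt$p.value, method = "approximate")
  }
}
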