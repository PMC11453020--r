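#' Simulation configuration for the synthetic PAV cohort
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe the cohort the generator is meant to emulate: three
#' population classes (wild, native, improved), exon-level depth around 20x
#' for present genes, and residual background coverage for absent genes kept
#' strictly below the 5% absence-call threshold so ground truth is
#' unambiguous.
#'
#' @param n_genes number of genes to simulate.
#' @param n_individuals_per_population named integer vector,
#'   population -> number of individuals.
#' @param population_class named character vector mapping each population to
#'   a class in `c("wild", "native", "improved")`. Defaults to matching
#'   names when the populations are named after classes.
#' @param frequency_spectrum genes x populations numeric matrix of target
#'   presence frequencies in `[0, 1]` (rownames = gene ids optional,
#'   colnames = population names), or `NULL` to draw a realistic spectrum
#'   with [default_frequency_spectrum()] (mostly fixed genes, some nearly
#'   fixed, a tail of common and rare dispensable genes).
#' @param mean_depth expected per-base depth (x) over exons of present
#'   genes; Poisson-distributed per base. `0` produces no coverage at all.
#' @param absent_residual_breadth maximum fraction of an absent gene's
#'   exonic bases that receive depth >= 2; must stay below 0.05 so residual
#'   coverage can never cross the absence-call boundary.
#' @param exons_per_gene integer range `c(min, max)` of exons per
#'   transcript.
#' @param exon_length integer range `c(min, max)` of exon lengths in bp.
#' @param seed RNG seed; identical seeds reproduce byte-identical outputs.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 200,
                       n_individuals_per_population = c(wild = 24, native = 40, improved = 20),
                       population_class = NULL,
                       frequency_spectrum = NULL,
                       mean_depth = 20,
                       absent_residual_breadth = 0.02,
                       exons_per_gene = c(2L, 6L),
                       exon_length = c(100L, 300L),
                       seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1)
    stop_config("n_genes", "must be a positive count")
  n_genes <- as.integer(n_genes)
  npp <- n_individuals_per_population
  if (is.null(names(npp)) || any(names(npp) == "") || any(npp < 1))
    stop_config("n_individuals_per_population", "must be a named vector of positive counts")
  npp <- setNames(as.integer(npp), names(npp))
  if (is.null(population_class)) {
    known <- c("wild", "native", "improved")
    population_class <- setNames(
      ifelse(names(npp) %in% known, names(npp), "native"), names(npp))
  }
  if (!all(names(npp) %in% names(population_class)))
    stop_config("population_class", "must name every population")
  if (!all(population_class %in% c("wild", "native", "improved")))
    stop_config("population_class", "values must be wild, native or improved")
  if (!is.numeric(mean_depth) || length(mean_depth) != 1 || mean_depth < 0)
    stop_config("mean_depth", "must be >= 0")
  if (!is.numeric(absent_residual_breadth) || absent_residual_breadth < 0 ||
      absent_residual_breadth >= 0.05)
    stop_config("absent_residual_breadth", "must lie in [0, 0.05) so it cannot cross the absence-call threshold")
  if (length(exons_per_gene) != 2 || any(exons_per_gene < 1) ||
      exons_per_gene[1] > exons_per_gene[2])
    stop_config("exons_per_gene", "must be an increasing range of counts >= 1")
  if (length(exon_length) != 2 || any(exon_length < 1) ||
      exon_length[1] > exon_length[2])
    stop_config("exon_length", "must be an increasing range of lengths >= 1 bp")
  seed <- as.integer(seed)

  if (!is.null(frequency_spectrum)) {
    fs <- as.matrix(frequency_spectrum)
    if (nrow(fs) != n_genes || ncol(fs) != length(npp))
      stop_config("frequency_spectrum", sprintf(
        "must be a %d x %d matrix (genes x populations)", n_genes, length(npp)))
    if (any(fs < 0 | fs > 1))
      stop_config("frequency_spectrum", "frequencies must lie in [0, 1]")
    if (is.null(colnames(fs))) colnames(fs) <- names(npp)
  } else {
    fs <- default_frequency_spectrum(n_genes, names(npp), seed = seed)
  }
  rownames(fs) <- sprintf("gene%04d", seq_len(n_genes))

  structure(list(
    n_genes = n_genes,
    n_individuals_per_population = npp,
    population_class = population_class,
    frequency_spectrum = fs,
    mean_depth = mean_depth,
    absent_residual_breadth = absent_residual_breadth,
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    seed = seed
  ), class = "sim_config")
}

#' Draw a realistic per-population presence-frequency spectrum
#'
#' Emulates the frequency structure seen in mammalian pan-genomes: the large
#' majority of genes fixed in every population (core), a slice nearly fixed
#' (softcore range), and a dispensable tail whose frequencies vary between
#' populations, including rare (<1%) genes.
#'
#' @param n_genes number of genes.
#' @param populations character vector of population names.
#' @param core_fraction fraction of genes fixed at 1.0 everywhere.
#' @param nearly_fixed_fraction fraction of genes at frequencies just below
#'   1 (0.97-0.999).
#' @param seed RNG seed.
#' @return genes x populations matrix of frequencies.
#' @export
default_frequency_spectrum <- function(n_genes, populations,
                                       core_fraction = 0.80,
                                       nearly_fixed_fraction = 0.05,
                                       seed = 1L) {
  withr::with_seed(seed + 104729L, {
    n_pop <- length(populations)
    n_core <- round(core_fraction * n_genes)
    n_nf <- round(nearly_fixed_fraction * n_genes)
    n_disp <- n_genes - n_core - n_nf
    fs <- matrix(1, nrow = n_genes, ncol = n_pop,
                 dimnames = list(NULL, populations))
    if (n_nf > 0) {
      rows <- n_core + seq_len(n_nf)
      fs[rows, ] <- matrix(runif(n_nf * n_pop, 0.97, 0.999), ncol = n_pop)
    }
    if (n_disp > 0) {
      rows <- n_core + n_nf + seq_len(n_disp)
      # Beta(0.6, 0.6): U-shaped, yields both common and rare dispensables
      fs[rows, ] <- matrix(rbeta(n_disp * n_pop, 0.6, 0.6), ncol = n_pop)
    }
    fs
  })
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  genes:", x$n_genes, "\n")
  cat("  individuals:", paste(sprintf("%s=%d (%s)",
      names(x$n_individuals_per_population),
      x$n_individuals_per_population,
      x$population_class[names(x$n_individuals_per_population)]),
      collapse = ", "), "\n")
  cat("  mean depth:", x$mean_depth, "x; residual breadth:",
      x$absent_residual_breadth, "\n")
  cat("  exons/gene:", paste(x$exons_per_gene, collapse = "-"),
      "; exon length:", paste(x$exon_length, collapse = "-"), "bp\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
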