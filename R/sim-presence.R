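#' Simulate ground-truth gene presence for a cohort
#'
#' Each gene/individual presence is an independent Bernoulli draw with the
#' gene's target frequency in that individual's population. Frequency 1
#' yields presence in every individual, frequency 0 in none.
#'
#' @param config a [sim_config()].
#' @return a list of class `pav_truth`: `presence` (genes x individuals 0/1
#'   integer matrix) and `popmap` (individual_id, population, class).
#' @export
simulate_presence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 2L, {
    npp <- config$n_individuals_per_population
    pops <- names(npp)
    ids <- unlist(lapply(pops, function(p)
      sprintf("%s%03d", p, seq_len(npp[[p]]))), use.names = FALSE)
    popmap <- data.table(
      individual_id = ids,
      population = rep(pops, npp),
      class = unname(config$population_class[rep(pops, npp)]))
    fs <- config$frequency_spectrum
    presence <- matrix(0L, nrow = config$n_genes, ncol = length(ids),
                       dimnames = list(rownames(fs), ids))
    for (p in pops) {
      cols <- which(popmap$population == p)
      f <- fs[, p]
      presence[, cols] <- matrix(
        rbinom(length(f) * length(cols), 1L, rep(f, times = length(cols))),
        nrow = length(f))
    }
    structure(list(presence = presence,
                   popmap = validate_population_map(popmap)),
              class = "pav_truth")
  })
}
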