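#' Simulate closed or open gene-pool presence matrices
#'
#' Fixtures for rarefaction/openness modelling with known structure.
#' `closed`: every individual carries exactly the same `core_size` genes, so
#' pan and core accumulation curves are flat at `core_size`. `open`: on top
#' of the shared core, each successive individual introduces
#' `Poisson(novelty_rate)` novel dispensable genes, and a gene introduced at
#' individual i is carried by each later individual independently with
#' probability 0.5 (geometric-decay sharing) — a saturating but open pool.
#'
#' @param core_size number of genes shared by all individuals (>= 0).
#' @param pool_model `"closed"` or `"open"`.
#' @param novelty_rate expected novel dispensable genes per new individual
#'   (open model only).
#' @param n_individuals cohort size.
#' @param seed RNG seed.
#' @param carry_prob probability that a later individual carries an already
#'   introduced dispensable gene.
#' @return an integer 0/1 matrix (genes x individuals) with attribute
#'   `total_genes` — core plus realized dispensable genes, the generating
#'   asymptote a saturation fit should recover.
#' @export
simulate_gene_pools <- function(core_size, pool_model = c("closed", "open"),
                                novelty_rate = 0, n_individuals, seed = 1L,
                                carry_prob = 0.5) {
  pool_model <- match.arg(pool_model)
  if (core_size < 0) stop_config("core_size", "must be >= 0")
  if (novelty_rate < 0) stop_config("novelty_rate", "must be >= 0")
  if (n_individuals < 1) stop_config("n_individuals", "must be >= 1")
  ids <- sprintf("ind%03d", seq_len(n_individuals))
  core <- matrix(1L, nrow = core_size, ncol = n_individuals,
                 dimnames = list(if (core_size) sprintf("core%04d", seq_len(core_size)),
                                 ids))
  if (pool_model == "closed") {
    attr(core, "total_genes") <- core_size
    return(core)
  }
  withr::with_seed(seed, {
    disp_rows <- list()
    k <- 0L
    for (i in seq_len(n_individuals)) {
      n_new <- rpois(1L, novelty_rate)
      if (n_new == 0) next
      later <- n_individuals - i
      block <- matrix(0L, nrow = n_new, ncol = n_individuals)
      block[, i] <- 1L
      if (later > 0)
        block[, (i + 1L):n_individuals] <-
          matrix(rbinom(n_new * later, 1L, carry_prob), nrow = n_new)
      rownames(block) <- sprintf("disp%04d", k + seq_len(n_new))
      k <- k + n_new
      disp_rows[[length(disp_rows) + 1L]] <- block
    }
    m <- if (length(disp_rows)) rbind(core, do.call(rbind, disp_rows)) else core
    colnames(m) <- ids
    attr(m, "total_genes") <- nrow(m)
    m
  })
}
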