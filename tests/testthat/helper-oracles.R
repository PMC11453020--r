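suppressPackageStartupMessages(library(data.table))

# Independent oracles and small fixture builders shared across test files.

# Two-sided Fisher p by direct enumeration over the hypergeometric support
# (probability-mass convention). Kept independent of fisher_exact_two_sided.
fisher_oracle <- function(a, b, c_, d) {
  m <- a + c_          # presence margin
  n <- b + d           # absence margin
  k <- a + b           # population-A margin
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to group A (no ties assumed).
mwu_oracle <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * length(b) / 2
  combos <- utils::combn(length(pooled), n_a)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Per-base brute-force breadth over a body's exons from a raw depth table.
breadth_oracle <- function(track, body_exons, min_depth = 2L) {
  pos <- unlist(Map(seq.int, body_exons$start + 1L, body_exons$end))
  pos <- sort(unique(pos))
  depths <- vapply(pos, function(p) {
    hit <- track[track$chrom == body_exons$chrom[1] & track$pos == p, ]
    if (nrow(hit)) hit$depth[1] else 0L
  }, integer(1))
  sum(depths >= min_depth) / length(pos)
}

tiny_config <- function(n_genes = 12, seed = 42L, ...) {
  sim_config(n_genes = n_genes,
             n_individuals_per_population = c(wild = 4, native = 5, improved = 3),
             seed = seed, ...)
}

# simulate a small cohort end to end, returning everything the caller tests need
tiny_cohort <- function(cfg = tiny_config()) {
  models <- simulate_gene_models(cfg)
  truth <- simulate_presence(cfg)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- simulate_depth(truth, models, cfg, dir)
  tracks <- lapply(paths, read_depth)
  names(tracks) <- names(paths)
  list(cfg = cfg, models = models, truth = truth, tracks = tracks,
       bodies = select_gene_bodies(models), dir = dir)
}
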