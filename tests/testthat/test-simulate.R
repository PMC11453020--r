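test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(exon_length = c(0, 10)), "exon_length")
  expect_error(sim_config(exons_per_gene = c(3, 1)), "exons_per_gene")
  expect_error(sim_config(absent_residual_breadth = 0.05),
               "absent_residual_breadth")
  expect_error(sim_config(mean_depth = -1), "mean_depth")
  expect_error(
    sim_config(n_genes = 3,
               frequency_spectrum = matrix(1.5, nrow = 3, ncol = 3)),
    "frequency_spectrum")
  expect_error(sim_config(n_individuals_per_population = c(5, 5)),
               "n_individuals_per_population")
})

test_that("gene models are reproducible, non-overlapping, and carry an isoform oracle", {
  cfg <- tiny_config(n_genes = 10, seed = 1)
  m1 <- simulate_gene_models(cfg)
  m2 <- simulate_gene_models(cfg)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  expect_identical(uniqueN(m1$gene_id), 10L)

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_bed12(m1, f1); write_bed12(m2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # genes do not overlap on the synthetic chromosome
  spans <- as.data.table(m1)[, .(s = min(start), e = max(end)), by = gene_id]
  setorder(spans, s)
  expect_true(all(head(spans$e, -1) <= tail(spans$s, -1)))

  # at least one gene has two transcripts of different exonic lengths,
  # and the recorded oracle is the longer one
  lens <- as.data.table(m1)[, .(len = sum(end - start)),
                            by = .(gene_id, transcript_id)]
  multi <- lens[, .N, by = gene_id][N > 1, gene_id]
  expect_gt(length(multi), 0)
  oracle <- attr(m1, "longest_transcript")
  for (g in multi) {
    two <- lens[gene_id == g]
    expect_gt(max(two$len), min(two$len))
    expect_identical(oracle[[g]], two[which.max(len), transcript_id])
  }
})

test_that("single-exon configuration yields exonic length equal to gene span", {
  cfg <- tiny_config(n_genes = 6, exons_per_gene = c(1, 1), seed = 3)
  m <- simulate_gene_models(cfg)
  per_tx <- as.data.table(m)[, .N, by = transcript_id]
  expect_true(all(per_tx$N == 1L))
  one_tx <- as.data.table(m)[grepl("t1$", transcript_id)]
  expect_equal(one_tx[, sum(end - start), by = gene_id]$V1,
               one_tx[, max(end) - min(start), by = gene_id]$V1)
})

test_that("presence draws honour the configured frequencies", {
  fs_one <- matrix(1, nrow = 5, ncol = 3)
  cfg <- tiny_config(n_genes = 5, frequency_spectrum = fs_one)
  truth <- simulate_presence(cfg)
  expect_true(all(truth$presence == 1L))

  fs_zero <- matrix(0, nrow = 5, ncol = 3)
  cfg0 <- tiny_config(n_genes = 5, frequency_spectrum = fs_zero)
  expect_true(all(simulate_presence(cfg0)$presence == 0L))

  # frequency 0.5 over 1000 individuals: realized within 3 binomial SDs
  cfg_half <- sim_config(n_genes = 4,
                         n_individuals_per_population = c(native = 1000),
                         frequency_spectrum = matrix(0.5, 4, 1), seed = 11)
  th <- simulate_presence(cfg_half)
  realized <- rowMeans(th$presence)
  sd3 <- 3 * sqrt(0.5 * 0.5 / 1000)
  expect_true(all(abs(realized - 0.5) <= sd3))
})

test_that("depth tracks separate present from absent genes at the breadth rule", {
  cfg <- tiny_config(n_genes = 8, seed = 5, absent_residual_breadth = 0.02)
  co <- tiny_cohort(cfg)
  ind <- colnames(co$truth$presence)[1]
  track <- co$tracks[[ind]]
  br <- exon_breadth(track, co$bodies, min_depth = 2L)
  present <- co$truth$presence[br$gene_id, ind] == 1L
  expect_true(all(br$breadth[present] >= 0.95))
  expect_true(all(br$breadth[!present] <= cfg$absent_residual_breadth))
  # separation: no breadth in the ambiguous band
  expect_false(any(br$breadth >= cfg$absent_residual_breadth + 1e-9 &
                   br$breadth < 0.95))
})

test_that("depth generation is byte-deterministic and checks gene ids", {
  cfg <- tiny_config(n_genes = 5, seed = 9)
  models <- simulate_gene_models(cfg)
  truth <- simulate_presence(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- simulate_depth(truth, models, cfg, d1)
  p2 <- simulate_depth(truth, models, cfg, d2)
  expect_identical(readLines(p1[[1]]), readLines(p2[[1]]))

  bad_truth <- truth
  rownames(bad_truth$presence) <- paste0("x", rownames(truth$presence))
  expect_error(simulate_depth(bad_truth, models, cfg, d1), "gene ids")
})

test_that("zero mean depth makes every gene absent everywhere", {
  cfg <- tiny_config(n_genes = 5, seed = 2, mean_depth = 0,
                     absent_residual_breadth = 0)
  co <- tiny_cohort(cfg)
  m <- build_presence_matrix(co$tracks, co$bodies)
  expect_true(all(m == 0L))
})

test_that("gene pools: closed pools are flat and open pools keep growing", {
  closed <- simulate_gene_pools(100, "closed", n_individuals = 30)
  expect_true(all(closed == 1L))
  expect_identical(dim(closed), c(100L, 30L))
  expect_identical(attr(closed, "total_genes"), 100)

  open <- simulate_gene_pools(50, "open", novelty_rate = 4,
                              n_individuals = 60, seed = 21)
  rr <- rarefy(open, iterations = 50, seed = 3)
  # pan curve strictly increasing in expectation for an open pool
  expect_true(all(diff(rr$summary$pan_mean) >= 0))
  expect_gt(rr$summary$pan_mean[60], rr$summary$pan_mean[1])

  one <- simulate_gene_pools(10, "open", novelty_rate = 2,
                             n_individuals = 1, seed = 4)
  r1 <- rarefy(one, iterations = 5, seed = 1)
  expect_identical(r1$pan, r1$core)

  expect_error(simulate_gene_pools(-1, "closed", n_individuals = 5),
               "core_size")
  expect_error(simulate_gene_pools(5, "open", novelty_rate = -2,
                                   n_individuals = 5), "novelty_rate")
})

test_that("contig fixture realizes planned boundaries and records an oracle", {
  x <- simulate_contigs_and_alignments(60, seed = 3)
  o <- x$oracle
  expect_identical(Biostrings::width(x$contigs),
                   as.integer(o$length[match(names(x$contigs), o$contig_id)]))
  # the planned boundary contigs exist
  expect_true(any(o$length == 500L & !o$keep))
  expect_true(any(o$length == 501L & o$keep))
  s <- summarize_alignments(x$ref_paf)
  expect_true(any(abs(s$identity - 0.90) < 1e-12 &
                  abs(s$coverage - 0.80) < 1e-12))
  # the exact-boundary self-redundant contig and twin pair
  sp <- summarize_alignments(x$self_paf, by = "pair")
  expect_true(any(abs(sp$identity - 0.90) < 1e-12 &
                  abs(sp$coverage - 0.90) < 1e-12))
  twins <- o[category == "twin"]
  expect_identical(nrow(twins), 2L)
  expect_identical(twins[keep == FALSE, contig_id], "twin0002")
  # determinism
  y <- simulate_contigs_and_alignments(60, seed = 3)
  expect_identical(as.data.frame(x$oracle), as.data.frame(y$oracle))
  expect_identical(as.data.frame(x$ref_paf), as.data.frame(y$ref_paf))
})
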