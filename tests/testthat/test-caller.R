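exon_table <- function(...) {
  validate_gene_models(rbindlist(list(...)))
}

tx <- function(gene, tx_id, starts, ends, chrom = "chr1") {
  data.table(gene_id = gene, transcript_id = tx_id, chrom = chrom,
             strand = "+", start = as.integer(starts), end = as.integer(ends))
}

test_that("gene body selection takes the longest transcript, ties by id", {
  m <- exon_table(
    tx("g1", "short", 0, 300),
    tx("g1", "long", c(1000, 1400), c(1300, 1600)),   # 300 + 200 = 500
    tx("g2", "tB", 5000, 5400),
    tx("g2", "tA", 6000, 6400),                        # tie at 400 -> tA
    tx("g3", "only", 9000, 9100))
  b <- select_gene_bodies(m)
  expect_identical(b[gene_id == "g1", unique(transcript_id)], "long")
  expect_identical(b[gene_id == "g1", unique(exonic_length)], 500L)
  expect_identical(b[gene_id == "g2", unique(transcript_id)], "tA")
  expect_identical(b[gene_id == "g3", unique(transcript_id)], "only")
})

test_that("individual retention uses mean depth over the full reference length", {
  t_at <- data.table(chrom = "chr1", pos = 1:100, depth = 10L)    # mean 10.00
  t_low <- data.table(chrom = "chr1", pos = 1:100, depth = c(rep(10L, 99), 9L))
  t_empty <- data.table(chrom = character(), pos = integer(), depth = integer())
  setkey(t_at, chrom, pos); setkey(t_low, chrom, pos); setkey(t_empty, chrom, pos)
  tracks <- list(at = t_at, low = t_low, none = t_empty)
  kept <- filter_individuals_by_depth(tracks, ref_length = 100)
  expect_identical(kept, "at")   # exactly 10x retained, 9.99x and 0x dropped
  expect_error(filter_individuals_by_depth(tracks, ref_length = NULL),
               "ref_length")
})

test_that("exon breadth matches a hand count and a brute-force oracle", {
  body <- select_gene_bodies(exon_table(tx("g1", "t1", 0, 100)))
  track <- read_depth(withr::local_tempfile(
    lines = sprintf("chr1\t%d\t5", 1:4)))
  br <- exon_breadth(track, body, min_depth = 2L)
  expect_equal(br$breadth, 0.04)

  full <- read_depth(withr::local_tempfile(
    lines = sprintf("chr1\t%d\t2", 1:100)))
  expect_equal(exon_breadth(full, body, 2L)$breadth, 1)
  ones <- read_depth(withr::local_tempfile(
    lines = sprintf("chr1\t%d\t1", 1:100)))
  expect_equal(exon_breadth(ones, body, 2L)$breadth, 0)

  # randomized small case against the per-base oracle
  withr::with_seed(99, {
    for (rep in 1:5) {
      ex <- tx("g", "t", c(10, 60), c(40, 90))
      body2 <- select_gene_bodies(exon_table(ex))
      pos <- sample(1:90, 40)
      tr <- data.table(chrom = "chr1", pos = sort(pos),
                       depth = sample(0:4, 40, TRUE))
      setkey(tr, chrom, pos)
      expect_equal(exon_breadth(tr, body2, 2L)$breadth,
                   breadth_oracle(tr, ex, 2L))
    }
  })
})

test_that("overlapping exons in a body are unioned, not double counted", {
  # overlapping exons [0,100) and [50,120) union to 120 exonic bases;
  # select_gene_bodies tolerates them (no validation) and must not sum to 170
  m <- tx("g1", "t1", c(0, 50), c(100, 120))
  body <- select_gene_bodies(m)
  expect_identical(body[, unique(exonic_length)], 120L)
})

test_that("the absence call is strict at the threshold", {
  cfg <- caller_config()
  expect_identical(call_presence(0.04, cfg), "absent")
  expect_identical(call_presence(0.05, cfg), "present")
  expect_identical(call_presence(1.0, cfg), "present")
  expect_error(call_presence(1.2, cfg))
  expect_error(caller_config(min_depth = 0), "min_depth")
  expect_error(caller_config(absence_breadth_threshold = 1), "threshold")
})

test_that("presence matrix recovers ground truth exactly on synthetic data", {
  for (rb in c(0, 0.04)) {
    cfg <- tiny_config(n_genes = 10, seed = 17, absent_residual_breadth = rb)
    co <- tiny_cohort(cfg)
    m <- build_presence_matrix(co$tracks, co$bodies)
    expect_identical(m[rownames(co$truth$presence), colnames(co$truth$presence)],
                     co$truth$presence)
  }
})

test_that("adding exonic depth never flips a present call to absent", {
  cfg <- tiny_config(n_genes = 6, seed = 23)
  co <- tiny_cohort(cfg)
  ind <- names(co$tracks)[1]
  base <- exon_breadth(co$tracks[[ind]], co$bodies, 2L)
  boosted <- copy(co$tracks[[ind]])[, depth := depth + 3L]
  setkey(boosted, chrom, pos)
  more <- exon_breadth(boosted, co$bodies, 2L)
  expect_true(all(more$breadth >= base$breadth))
  was_present <- call_presence(base$breadth) == "present"
  expect_true(all(call_presence(more$breadth)[was_present] == "present"))
})

test_that("missing tracks error and empty cohorts warn", {
  cfg <- tiny_config(n_genes = 4, seed = 31)
  co <- tiny_cohort(cfg)
  expect_error(build_presence_matrix(co$tracks, co$bodies,
                                     individuals = c(names(co$tracks), "ghost")),
               "ghost")
  expect_warning(
    m0 <- build_presence_matrix(co$tracks, co$bodies, individuals = character()),
    "no retained individuals")
  expect_identical(ncol(m0), 0L)
  expect_identical(nrow(m0), 4L)
})
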