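paf_row <- function(q, qlen, qs, qe, t, tlen, matches, block) {
  data.table(query_id = q, query_len = as.integer(qlen),
             query_start = as.integer(qs), query_end = as.integer(qe),
             strand = "+", target_id = t, target_len = as.integer(tlen),
             target_start = 0L, target_end = as.integer(qe - qs),
             matches = as.integer(matches), block_len = as.integer(block),
             mapq = 60L)
}

test_that("length retention is strictly greater than 500 bp", {
  lens <- c(a = 499L, b = 500L, c = 501L, d = 5000L)
  expect_identical(filter_by_length(lens), c("c", "d"))
  expect_identical(filter_by_length(setNames(integer(), character())),
                   character())
})

test_that("alignment summaries use interval union and weighted identity", {
  paf <- rbind(paf_row("ctg", 200, 0, 100, "ref", 1e6, 95, 100),
               paf_row("ctg", 200, 50, 150, "ref", 1e6, 80, 100))
  s <- summarize_alignments(paf)
  expect_equal(s$coverage, 150 / 200)
  expect_equal(s$identity, (95 + 80) / 200)

  single <- summarize_alignments(paf_row("c1", 100, 0, 100, "ref", 1e6, 90, 100))
  expect_equal(single$identity, 0.90)

  none <- summarize_alignments(empty <- paf[0])
  expect_identical(nrow(none), 0L)
})

test_that("reference redundancy needs both thresholds (inclusive)", {
  s <- data.table(query_id = c("x", "y", "z"),
                  query_len = 1000L,
                  coverage = c(0.85, 0.10, 0.80),
                  identity = c(0.95, 0.95, 0.90))
  expect_setequal(filter_reference_redundant(s), c("x", "z"))
})

test_that("self redundancy removes the shorter contig with deterministic ties", {
  lens <- c(big = 2000L, small = 1000L)
  paf <- paf_row("small", 1000, 0, 950, "big", 2000, 874, 950)  # id 0.92
  expect_identical(filter_self_redundant(paf, lens), "small")

  twins <- c(tw_a = 1500L, tw_b = 1500L)
  tp <- paf_row("tw_b", 1500, 0, 1500, "tw_a", 1500, 1500, 1500)
  expect_identical(filter_self_redundant(tp, twins), "tw_b")

  # mutually non-overlapping contigs: nothing removed
  lens2 <- c(p = 1200L, q = 900L)
  weak <- paf_row("q", 900, 0, 400, "p", 1200, 396, 400)  # coverage 0.44
  expect_identical(filter_self_redundant(weak, lens2), character())
})

test_that("cascading removals keep contigs whose only partner was removed", {
  # B redundant to A; C redundant to B only. B is removed by A, so C stays.
  lens <- c(A = 3000L, B = 2000L, C = 1000L)
  paf <- rbind(paf_row("B", 2000, 0, 1900, "A", 3000, 1800, 1900),
               paf_row("C", 1000, 0, 980, "B", 2000, 940, 980))
  expect_identical(sort(filter_self_redundant(paf, lens)), "B")
})

test_that("filters are idempotent and compose in the documented order", {
  x <- simulate_contigs_and_alignments(80, seed = 12)
  lens <- setNames(x$oracle$length, x$oracle$contig_id)
  r1 <- filter_contigs(lens, x$ref_paf, x$self_paf)
  r2 <- filter_contigs(lens[r1$kept],
                       x$ref_paf[query_id %in% r1$kept],
                       x$self_paf[query_id %in% r1$kept &
                                  target_id %in% r1$kept])
  expect_identical(sort(r2$kept), sort(r1$kept))
  expect_true(all(r2$report$keep))

  # drop reasons recorded per contig
  expect_false(anyNA(r1$report[keep == FALSE, drop_reason]))
  expect_true(all(r1$report[keep == TRUE, is.na(drop_reason)]))
})

test_that("retained set equals the generator oracle, including an exclusion list", {
  x <- simulate_contigs_and_alignments(120, seed = 77)
  lens <- setNames(x$oracle$length, x$oracle$contig_id)
  res <- filter_contigs(lens, x$ref_paf, x$self_paf)
  expect_identical(sort(res$kept), sort(x$oracle[keep == TRUE, contig_id]))
  merged <- merge(res$report, x$oracle, by = "contig_id")
  expect_identical(merged$drop_reason.x, merged$drop_reason.y)

  # an external exclusion list is applied before everything else
  drop_one <- x$oracle[keep == TRUE, contig_id][1]
  res2 <- filter_contigs(lens, x$ref_paf, x$self_paf,
                         exclude_list = drop_one)
  expect_false(drop_one %in% res2$kept)
  expect_identical(res2$report[contig_id == drop_one, drop_reason], "excluded")
})
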