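test_that("presence frequencies are exact rationals with half-up display", {
  m <- matrix(0L, nrow = 3, ncol = 121,
              dimnames = list(c("gA", "gB", "gC"), sprintf("i%03d", 1:121)))
  m["gA", 1:120] <- 1L
  m["gB", ] <- 1L
  m["gC", 1:78] <- 1L
  fq <- presence_frequency(m)
  expect_equal(fq$frequency, c(120, 121, 78) / 121)
  expect_equal(percent(fq$frequency), c(99.17, 100.00, 64.46))
  expect_equal(percent(117 / 121), 96.69)

  expect_error(presence_frequency(m, character()), "empty")
  expect_error(presence_frequency(m, "nobody"), "nobody")
  sub <- presence_frequency(m, sprintf("i%03d", 1:10))
  expect_identical(unique(sub$n_total), 10L)
})

test_that("category boundaries partition a 277-individual cohort correctly", {
  n <- 277L
  counts <- c(277L, 276L, 275L, 274L, 138L, 3L, 2L, 1L, 0L)
  fq <- data.table(gene_id = sprintf("g%d", counts), n_present = counts,
                   n_total = n, frequency = counts / n)
  cls <- classify_genes(fq)
  # 0.99 * 277 = 274.23 so softcore needs count >= 275; 0.01 * 277 = 2.77
  expect_identical(as.character(cls$category),
                   c("core", "softcore", "softcore", "shell", "shell",
                     "shell", "cloud", "cloud", "cloud"))
  expect_true(cls[n_present == 0L, zero_presence])
})

test_that("every gene receives exactly one category on random inputs", {
  withr::with_seed(7, {
    for (n_total in c(10L, 101L, 277L)) {
      counts <- sample(0:n_total, 200, replace = TRUE)
      fq <- data.table(gene_id = sprintf("g%04d", seq_along(counts)),
                       n_present = counts, n_total = n_total,
                       frequency = counts / n_total)
      cls <- classify_genes(fq)
      expect_false(anyNA(cls$category))
      smry <- category_summary(cls)
      expect_identical(sum(smry$n), 200L)
      expect_identical(attr(smry, "total_genes") -
                         smry[category == "core", n],
                       attr(smry, "dispensable_genes"))
    }
  })
})

test_that("category summary reproduces printed-count arithmetic", {
  smry <- category_summary(c(core = 23098, softcore = 914, shell = 867,
                             cloud = 864))
  expect_identical(attr(smry, "total_genes"), 25743L)
  expect_identical(attr(smry, "dispensable_genes"), 2645L)
  expect_equal(smry$pct, c(89.73, 3.55, 3.37, 3.36))
})

test_that("per-individual gene counts equal truth column sums", {
  cfg <- tiny_config(n_genes = 10, seed = 29)
  truth <- simulate_presence(cfg)
  counts <- per_individual_gene_count(truth$presence)
  expect_identical(unname(counts), unname(as.integer(colSums(truth$presence))))

  allm <- matrix(1L, 4, 3, dimnames = list(letters[1:4], c("x", "y", "z")))
  expect_identical(unname(per_individual_gene_count(allm)), rep(4L, 3))
  expect_identical(unname(per_individual_gene_count(allm * 0L)), rep(0L, 3))

  wild_only <- per_individual_gene_count(truth$presence, truth$popmap, "wild")
  expect_identical(names(wild_only),
                   truth$popmap[class == "wild", individual_id])
  expect_error(per_individual_gene_count(truth$presence, truth$popmap,
                                         "feral"), "feral")
})

test_that("Mann-Whitney U matches enumeration and handles ties by approximation", {
  same <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6) - 3)
  expect_gte(same$p, 0.99)

  sep <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_identical(sep$U, 0)
  expect_equal(sep$p, 0.1)     # 2 * (1 / choose(6, 3))
  expect_identical(sep$method, "exact")

  swapped <- mann_whitney_u(c(10, 11, 12), c(1, 2, 3))
  expect_identical(swapped$U, 9)          # n_a * n_b - U
  expect_equal(swapped$p, sep$p)

  # exact path equals brute-force enumeration for all sizes up to 6
  withr::with_seed(5, {
    for (n_a in 2:6) for (n_b in 2:6) {
      vals <- sample(1000, n_a + n_b)     # distinct -> no ties
      a <- vals[seq_len(n_a)]; b <- vals[-seq_len(n_a)]
      got <- mann_whitney_u(a, b)
      expect_identical(got$method, "exact")
      expect_equal(got$p, mwu_oracle(a, b))
    }
  })

  tied <- mann_whitney_u(c(1, 2, 2, 3), c(2, 3, 4, 4))
  expect_identical(tied$method, "approximate")
  ref <- suppressWarnings(wilcox.test(c(1, 2, 2, 3), c(2, 3, 4, 4),
                                      exact = FALSE, correct = TRUE))
  expect_equal(tied$p, ref$p.value)
})
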