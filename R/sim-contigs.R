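#' Simulate nonreference contigs with alignment fixtures and a keep/drop oracle
#'
#' Builds a contig set spanning the map-to-pan curation rules: `short`
#' contigs (<= 500 bp, dropped by the length rule), `ref_redundant` contigs
#' (reference alignment with identity >= 0.90 and coverage >= 0.80,
#' excluded), `self_redundant` contigs (covered >= 0.90 at identity >= 0.90
#' by a longer clean contig, removed), and `clean` contigs that survive
#' every filter. With `boundary_cases = TRUE` the fixture deterministically
#' includes the decision-boundary contigs: lengths exactly 500 and 501,
#' reference hits at exactly (0.90, 0.80) and just outside on either margin,
#' a self hit at exactly (0.90, 0.90), and an identical-twin pair of equal
#' length (exactly one twin survives).
#'
#' The oracle is computed from the generator's own realized integer
#' arithmetic (alignment spans and match counts), not from the filter code,
#' so filter results can be compared against it.
#'
#' @param n_contigs total number of contigs.
#' @param redundancy_plan named numeric vector of proportions (or counts)
#'   for categories `short`, `ref_redundant`, `self_redundant`, `clean`.
#' @param seed RNG seed.
#' @param boundary_cases include the deterministic boundary contigs.
#' @return list with `contigs` (Biostrings::DNAStringSet), `ref_paf`,
#'   `self_paf` (PAF data.tables), and `oracle` (contig_id, category,
#'   length, keep, drop_reason).
#' @export
simulate_contigs_and_alignments <- function(n_contigs = 200,
                                            redundancy_plan = c(short = 0.15,
                                                                ref_redundant = 0.30,
                                                                self_redundant = 0.20,
                                                                clean = 0.35),
                                            seed = 1L,
                                            boundary_cases = TRUE) {
  cats <- c("short", "ref_redundant", "self_redundant", "clean")
  if (!setequal(names(redundancy_plan), cats) || any(redundancy_plan < 0))
    stop_config("redundancy_plan", "must give non-negative weights for short, ref_redundant, self_redundant, clean")
  counts <- if (sum(redundancy_plan) > 4) round(redundancy_plan[cats]) else {
    n <- floor(redundancy_plan[cats] / sum(redundancy_plan) * n_contigs)
    n["clean"] <- n["clean"] + (n_contigs - sum(n))
    n
  }
  if (sum(counts) != n_contigs)
    stop_config("redundancy_plan", "counts must sum to n_contigs")
  if (counts["self_redundant"] > 0 && counts["clean"] < 2)
    stop_config("redundancy_plan", "self-redundant contigs need clean partners")

  withr::with_seed(seed, {
    category <- rep(cats, counts)
    n <- length(category)
    id <- sprintf("ctg%04d", seq_len(n))
    len <- integer(n)
    len[category == "short"] <- sample(100:500, sum(category == "short"), TRUE)
    len[category == "ref_redundant"] <- sample(600:3000, sum(category == "ref_redundant"), TRUE)
    len[category == "self_redundant"] <- sample(600:2500, sum(category == "self_redundant"), TRUE)
    len[category == "clean"] <- sample(3001:5000, sum(category == "clean"), TRUE)

    plan <- data.table(contig_id = id, category = category, length = len,
                       tgt_id = NA_real_, tgt_cov = NA_real_,
                       partner = NA_character_)
    plan[category == "ref_redundant",
         `:=`(tgt_id = runif(.N, 0.91, 0.99), tgt_cov = runif(.N, 0.82, 0.99))]
    plan[category == "self_redundant",
         `:=`(tgt_id = runif(.N, 0.91, 0.99), tgt_cov = runif(.N, 0.92, 0.99))]
    # half the clean contigs get a reference hit failing the AND rule
    clean_idx <- which(plan$category == "clean")
    decoy <- clean_idx[seq_along(clean_idx) %% 2L == 0L]
    if (length(decoy)) {
      plan[decoy, `:=`(tgt_id = runif(.N, 0.91, 0.99),
                       tgt_cov = runif(.N, 0.05, 0.50))]
    }
    if (boundary_cases && all(counts >= c(short = 2, ref_redundant = 3,
                                          self_redundant = 2, clean = 3))) {
      i_short <- which(category == "short")
      plan[i_short[1], length := 500L]                        # dropped: not > 500
      i_ref <- which(category == "ref_redundant")
      plan[i_ref[1], `:=`(length = 1000L, tgt_id = 0.90, tgt_cov = 0.80)]
      i_clean <- which(category == "clean")
      plan[i_clean[1], `:=`(length = 501L, tgt_id = NA_real_, tgt_cov = NA_real_)]
      plan[i_clean[2], `:=`(length = 1000L, tgt_id = 0.90, tgt_cov = 0.79)]
      plan[i_clean[3], `:=`(length = 1000L, tgt_id = 0.89, tgt_cov = 0.95)]
      i_self <- which(category == "self_redundant")
      plan[i_self[1], `:=`(length = 1000L, tgt_id = 0.90, tgt_cov = 0.90)]
    }
    # assign partners for self-redundant contigs among undecoyed clean contigs
    hosts <- plan[category == "clean" & is.na(tgt_id) & length > 2500,
                  contig_id]
    if (plan[category == "self_redundant", .N] > 0 && length(hosts) == 0)
      stop_config("redundancy_plan", "no clean contig available as self-redundancy partner")
    plan[category == "self_redundant",
         partner := rep(hosts, length.out = .N)]

    # realize reference PAF from targets using integer arithmetic
    ref_rows <- plan[category %in% c("ref_redundant", "clean") & !is.na(tgt_id)]
    ref_paf <- if (nrow(ref_rows)) ref_rows[, {
      qend <- as.integer(round(tgt_cov * length))
      block <- qend
      .(query_id = contig_id, query_len = length, query_start = 0L,
        query_end = qend, strand = "+", target_id = "ref", target_len = 10000000L,
        target_start = 0L, target_end = qend,
        matches = as.integer(round(tgt_id * block)), block_len = block,
        mapq = 60L)
    }] else empty_paf()

    # self PAF: redundant query vs longer clean partner
    self_rows <- plan[category == "self_redundant"]
    plen <- setNames(plan$length, plan$contig_id)
    self_paf <- if (nrow(self_rows)) self_rows[, {
      qend <- as.integer(round(tgt_cov * length))
      block <- qend
      .(query_id = contig_id, query_len = length, query_start = 0L,
        query_end = qend, strand = "+", target_id = partner,
        target_len = plen[partner], target_start = 0L, target_end = qend,
        matches = as.integer(round(tgt_id * block)), block_len = block,
        mapq = 60L)
    }] else empty_paf()

    if (boundary_cases && counts["clean"] >= 5) {
      # identical twin pair: same length, full mutual identity; the
      # lexicographically larger id is the removal candidate
      twin_len <- 1500L
      twins <- sprintf("twin%04d", 1:2)
      plan <- rbind(plan,
        data.table(contig_id = twins, category = "twin", length = twin_len,
                   tgt_id = NA_real_, tgt_cov = NA_real_, partner = NA_character_))
      self_paf <- rbind(self_paf, data.table(
        query_id = twins[2], query_len = twin_len, query_start = 0L,
        query_end = twin_len, strand = "+", target_id = twins[1],
        target_len = twin_len, target_start = 0L, target_end = twin_len,
        matches = twin_len, block_len = twin_len, mapq = 60L))
    }

    # oracle from realized arithmetic
    oracle <- copy(plan)[, keep := TRUE][, drop_reason := NA_character_]
    oracle[length <= 500L, `:=`(keep = FALSE, drop_reason = "short")]
    if (nrow(ref_paf)) {
      rid <- ref_paf[, .(r_id = matches / block_len,
                         r_cov = query_end / query_len), by = query_id]
      drop_ref <- rid[r_id >= 0.90 & r_cov >= 0.80, query_id]
      oracle[contig_id %in% drop_ref & keep,
             `:=`(keep = FALSE, drop_reason = "reference_redundant")]
    }
    if (nrow(self_paf)) {
      sid <- self_paf[, .(r_id = matches / block_len,
                          r_cov = query_end / query_len,
                          target_id = target_id[1]), by = query_id]
      keep_now <- oracle[keep == TRUE, contig_id]
      drop_self <- sid[r_id >= 0.90 & r_cov >= 0.90 &
                       query_id %in% keep_now & target_id %in% keep_now,
                       query_id]
      oracle[contig_id %in% drop_self,
             `:=`(keep = FALSE, drop_reason = "self_redundant")]
    }

    seqs <- Biostrings::DNAStringSet(vapply(oracle$length, function(L)
      paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""), ""))
    names(seqs) <- oracle$contig_id
    list(contigs = seqs,
         ref_paf = validate_paf(ref_paf),
         self_paf = validate_paf(self_paf),
         oracle = oracle[, .(contig_id, category, length, keep, drop_reason)])
  })
}

empty_paf <- function() {
  data.table(query_id = character(), query_len = integer(),
             query_start = integer(), query_end = integer(),
             strand = character(), target_id = character(),
             target_len = integer(), target_start = integer(),
             target_end = integer(), matches = integer(),
             block_len = integer(), mapq = integer())
}
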