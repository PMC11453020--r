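---
title: "Methods: coverage-based gene PAV analysis and pan-genome modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based gene PAV analysis and pan-genome modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pavkit implements a map-to-pan style analysis of gene presence/absence
variation (PAV) in resequenced cohorts — the kind of pipeline used to study
gene loss during domestication in livestock. This vignette is the package's
account of the methods: the models, the parameters that matter, the
numerical conventions, and what the synthetic-data generator does and does
not establish about real data.

## The presence/absence call

The caller follows the SGSGeneloss convention. For each gene the *gene
body* is the exon set of its longest transcript (greatest exonic length
after unioning overlapping exons; ties broken by the lexicographically
smallest transcript id, so the choice is deterministic). For one
individual, the *breadth* of a gene is

$$ b = \frac{\#\{\text{exonic bases with depth} \ge d_{\min}\}}{\text{exonic length}} $$

and the gene is called **absent** when $b < t$, **present** otherwise.
Defaults are $d_{\min} = 2$ reads and $t = 0.05$: a gene is absent when
fewer than 5% of its exonic bases are covered by at least two reads.
Two conventions are fixed deliberately:

* "covered by a minimum of two reads" is interpreted as per-base depth
  $\ge 2$ — depth is the only information in a samtools-depth track, and it
  is what SGSGeneloss uses;
* the absence rule is a strict inequality ("less than 5%"), so a breadth of
  exactly 0.05 is called present.

Before calling, individuals are filtered on genome-wide mean depth
$\ge 10\times$, where the mean divides the summed per-base depth by a total
reference length supplied by the caller — the usual meaning of "average
sequencing depth", not a mean over covered positions only. Depth tracks
use the samtools-depth dialect: 1-based positions, zero-depth positions
omitted; the package treats missing positions as depth 0. All internal
coordinates are 0-based half-open; BED12 and GFF3 input are converted at
the boundary so the same exon yields the same internal interval from
either format.

## Pan-genome categories

With presence frequencies computed over the full retained cohort, genes are
classified as

| category | frequency rule |
|----------|----------------|
| core     | exactly 100% (present in every retained individual) |
| softcore | more than 99% but less than 100% |
| shell    | 1% to 99%, both ends inclusive |
| cloud    | less than 1% |

Taking the shell interval closed on both ends makes the four categories a
true partition of [0, 1]; softcore is the open interval (0.99, 1). Genes
present in no retained individual satisfy the cloud rule literally and are
assigned cloud, with a `zero_presence` flag so the anomaly stays visible.
Displayed percentages round half-up to two decimals throughout the package
(`percent()`), matching how such tables are conventionally printed; the
underlying frequencies stay exact rationals. Note that softcore and cloud
are only *reachable* in large cohorts — with fewer than 100 individuals no
frequency can lie strictly between 99% and 100%.

Per-individual detected-gene counts are compared between population
classes with a two-sided Mann–Whitney U test: the exact null distribution
of U is used when $n_a n_b \le 400$ and there are no ties, otherwise the
normal approximation with tie and continuity corrections.

## Rarefaction and openness

`rarefy()` draws, for every sample size $n = 1 \dots N$ and each of 200
iterations (the conventional choice for cohorts of a few hundred), a
uniform sample of $n$ individuals without replacement and records the pan
size (genes present in at least one sampled individual) and core size
(genes present in all). Internally one random permutation per iteration is
accumulated, so each size-$n$ prefix is a valid uniform sample and the
curve costs a single pass; the mean pan curve agrees with
`vegan::specaccum(method = "random")`, which the tests verify.

No standard functional form exists for "the" pan-genome model, and an
estimated finite total is wanted; a pure power law cannot provide one. The
package therefore fits the bounded exponential

$$ P(n) = A - B e^{-n/\tau} $$

to the per-$n$ mean pan curve by constrained nonlinear least squares
($A \ge \max_n P(n)$, $B \ge 0$, $\tau > 0$), reporting $A$ as the
estimated total. Means rather than all iteration points are fitted because
the mean curve is what accumulation plots display; per-$n$ SDs are reported
but not used as weights. Alongside, Heaps' law $P(n) = D n^{\gamma}$ is fit
on $n \ge 2$ by log-log regression, and the pool is called **open** when
the largest observed mean pan size is still below 99% of $A$ or
$\gamma > 0.02$ — the conventional "still growing" reading. An exactly flat
curve short-circuits to the degenerate fit ($B = 0$, $A$ = the constant);
genuine non-convergence raises an error rather than silently falling back.

## Selection scan

For each gene, presence/absence counts in a reference population (wild
Bezoar for domestication; native goats for improvement) and a derived
population form a 2×2 table tested with a two-sided Fisher exact test
under the probability-mass convention (all tables with the same margins
whose point probability does not exceed the observed one) — the dominant
convention, stated explicitly because alternatives exist. Whether such
scans are one- or two-sided is often left unstated; two-sided is assumed
here. Genes at raw $P < 0.005$ are significant; no multiple-testing
correction enters the significance flag (matching the raw-P practice for
this scan), but a Benjamini–Hochberg q column is emitted for transparency.
Significant genes are **favorable** when the derived-population frequency
is higher than the reference, **unfavorable** when lower; identical
frequencies give direction "none" (guarded even though such genes cannot
reach significance).

## Nonreference contig curation

The map-to-pan cascade keeps contigs strictly longer than 500 bp, then
excludes contigs aligning to the reference with identity $\ge 90\%$ *and*
coverage $\ge 80\%$ (both inclusive), then removes self-redundant contigs
(identity $\ge 90\%$ and coverage $\ge 90\%$ against another contig). At
the multi-alignment level, coverage is the fraction of the contig inside
the union of its aligned intervals and identity is the block-length-
weighted mean of per-alignment matches/block-length — deterministic and
order-independent definitions. For self-redundancy the aligned coverage
describes the query contig, so a qualifying pair removes the query when it
is the shorter contig (at equal length, the lexicographically larger id);
contigs are processed in decreasing length order and can only be removed
by a partner that itself survives, so cascades resolve deterministically
and exactly one of two identical twins is kept. Which copy survives such a
deduplication is genuinely underdetermined in practice; keeping the longer
contig is this package's fixed rule. External contamination screens are
out of scope; a pre-made exclusion list can be supplied instead and is
applied before everything else.

## The synthetic-data generator

Every stage is testable without sequencing data because the generator
produces cohorts with known ground truth:

* **Gene models** — non-overlapping multi-exon genes on one synthetic
  chromosome; a third of genes get a second, strictly shorter isoform so
  longest-transcript selection is exercised with a by-construction oracle.
* **Presence** — independent Bernoulli draws per gene and individual from
  per-population target frequencies. The default spectrum puts 80% of
  genes at frequency 1 everywhere, 5% nearly fixed (0.97–0.999), and the
  rest on a U-shaped Beta(0.6, 0.6) so both common and rare dispensable
  genes occur — the frequency structure typical of mammalian pan-genomes,
  where roughly nine genes in ten are core.
* **Depth** — present genes receive i.i.d. Poisson(`mean_depth`) depth per
  exonic base (default 20×, a typical resequencing depth comfortably above
  the 10× retention filter); absent genes receive a contiguous block of
  depth 2 spanning `absent_residual_breadth` of their exonic length
  (default 2%). The contiguous block is the simplest adversarial layout
  for a breadth computation; the config refuses residual breadths at or
  above 0.05 so generated breadths can never cross the calling threshold,
  which is what makes exact ground-truth recovery a meaningful test. No
  published noise model exists for residual coverage of absent genes; this
  block model is a declared stand-in.
* **Gene pools** — a closed pool gives every individual the same core set
  (flat accumulation curves); an open pool adds Poisson(`novelty_rate`)
  novel dispensable genes per successive individual, each carried by later
  individuals with probability 0.5, giving a visibly saturating-but-open
  curve at desk scale whose generating asymptote (core plus realized novel
  genes) the saturation fit must recover.
* **Contigs** — a plan over the four curation categories realized through
  integer arithmetic (alignment spans and match counts), including exact
  boundary contigs: lengths 500/501, reference hits at exactly
  (0.90, 0.80) and just outside, a self hit at exactly (0.90, 0.90), and
  an identical-twin pair.

The generator is seeded end to end; identical seeds reproduce identical
files byte for byte. What it does **not** emulate: read-level artefacts
(mapping bias, duplicates, GC effects), partial gene loss and CNV dosage,
linkage between genes, population structure beyond per-population
frequencies, and intergenic coverage. Because simulated reads cover exons
only, the analysis scripts use the total exonic length as the denominator
of the mean-depth filter. Passing the recovery tests therefore shows the
*rules* are implemented exactly, not that the caller is robust to
real-data noise sources it never sees.

## Problem sizes and numerical choices

The shipped analyses and tests run at desk scale, chosen so the full suite
completes in about a minute: a 200-gene × 84-individual cohort for the
workflow scripts; 50 genes × 60 individuals for caller ground-truth
recovery; rarefaction with 200 iterations up to N = 100; exhaustive Fisher
enumeration over all 2×2 tables with margins ≤ 12; a 1,000-gene null scan
at the study's 24-vs-121 sample sizes replicated 10 times; and a
200-contig curation fixture. Headline cohort-scale numbers (tens of
thousands of genes over hundreds of individuals) require the corresponding
real matrices and are deliberately not targets of the test suite; what the
suite establishes is exact rule compliance, oracle agreement, and
parameter recovery under known generating conditions.

Smaller conventions, fixed once: percentages round half away from zero to
two decimals; frequency comparisons for category boundaries use exact
counts (core is `n_present == n_total`, never a floating-point equality);
the Fisher oracle comparison allows the same 1e-7 relative slack on the
point-probability comparison that the reference implementation uses; and
every stochastic routine takes an explicit seed and restores the caller's
RNG state.

## Limitations

* The absence call is binary; heterozygous loss and partial deletions are
  collapsed into present/absent at the 5% breadth boundary.
* The mean-depth filter needs the caller to supply the reference length;
  the package does not second-guess how depth was computed upstream
  (MAPQ or duplicate filters are the depth producer's responsibility).
* The saturation model is a descriptive fit; its asymptote is an
  extrapolation and inherits the usual caveats when the observed curve is
  far from saturation.
* The self-redundancy rule is pairwise; a contig covered 90% only by the
  union of several partners is not removed.
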