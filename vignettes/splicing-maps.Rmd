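---
title: "Position-dependent RBP binding and splicing maps: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-dependent RBP binding and splicing maps: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicebind)
```

This vignette explains the statistical model behind each stage of the
package, the parameters that matter, the numerical choices at degenerate
or ambiguous inputs, and what the synthetic-data tests do and do not
demonstrate about real data.

## The scientific question

Splicing-regulatory RBPs such as the RBFOX family act position
dependently: binding in the intron downstream of an alternative exon
tends to promote its inclusion, binding upstream tends to promote
skipping. Given (a) differential-splicing calls between a control and an
RBP-depleted condition and (b) CLIP peaks for the same RBP, the package
asks three questions: is the RBP's sequence element enriched near the
regulated exons; is binding positionally enriched in the flanks predicted
by the rule above; and which genes are direct targets (bound *and*
differentially spliced).

## Event filtering

An event is **significant** when FDR < 0.05 (strict), |ΔPSI| ≥ a
threshold (0.01 or 0.05 by convention; both supported), and the junction
reads (inclusion + skipping) summed over replicates reach 20 in at least
one condition. It is **insensitive** when FDR > 0.05 (strict) under the
same read rule; events at exactly FDR = 0.05 fall in neither set. Two
readings of the read rule are possible — per-replicate minimum or
per-condition sum — and the per-condition sum is used because replicate
counts in these tables are often uneven; the rule is a function argument
if the other reading is wanted. The insensitive set also keeps the read
floor so that the null exons are measurable to the same standard as the
tested exons (removable via `apply_read_floor = FALSE`).

ΔPSI is defined as mean PSI(condition 1 = control) − mean PSI(condition 2
= depleted). The sign of an rMATS `IncLevelDifference` depends on the
order in which the conditions were given to the caller, so the condition
order is a declared convention, not something inferable from the table.
Under this convention ΔPSI > 0 means the exon is *included* when the RBP
is present — the RBP promotes inclusion — and ΔPSI < 0 means *skipped*.

Cross-dataset gene matching is by symbol, case-insensitively, since
identifiers differ across genome builds and platforms; event matching is
exact on (type, contig, strand, regulated-exon coordinates), so a 1-nt
coordinate shift does not match. This strictness is deliberate: fuzzy
exon matching silently merges distinct splice sites.

## K-mer enrichment

All 4^k k-mers are counted in step-1 sliding windows over the flank
sequences; windows containing `N` are excluded from both count and total.
For k-mer *w* with foreground count `x` out of `n` windows, the
background probability is pseudocounted,

    p_w = (bg_count_w + c) / (bg_total + c * 4^k),   c = 1 by default,

and the one-sided p-value is the exact binomial upper tail
P(X ≥ x), X ~ Binomial(n, p_w), Bonferroni-corrected over the 4^k tests.
Counts are pooled across exons (a window-level test, one test per k-mer)
rather than per-exon presence/absence: the quantity of interest is the
overall density of the element in the flank class. Depletion appears as
enrichment < 1 and is not separately tested. The pseudocount matters when
4^k is comparable to the window total — enrichment values are then
shrunk toward the background — so enrichment ratios should be read
qualitatively at small sample sizes while the p-values remain exact for
the stated null.

Two foreground conventions are provided. The descriptive scan
(`run_pipeline()`'s k-mer stage) tests each flank side of all significant
cassette exons over 200 nt, the classical single-side picture. The
recovery scan (`regulatory_flank_kmer_test()`) pools the *regulatory*
side per class — downstream of included exons with upstream of skipped
exons — over the 150-nt flank, which is the coherent pooling under the
position-dependent model and is what the acceptance checks use; a
single-side scan dilutes the signal with the class whose element sits on
the other side.

Under-peak 6-mer enrichment uses the sense-strand sequence beneath each
peak. The default background takes same-width regions shifted two peak
widths downstream on the same strand, clipped to the containing gene —
locality controls composition. The alternative resamples each peak
sequence through its own first-order Markov (dinucleotide) chain; this
preserves dinucleotide composition in expectation rather than exactly,
which is sufficient for a background and much simpler than an exact
Eulerian-path shuffle.

## Peak handling

Peaks are BED6+2 (0-based half-open) with log2 fold change over a
size-matched input and a p-value; fold enrichment is 2^log2fc. The
stringent filter keeps fold enrichment ≥ 2 (inclusive) and p < 1e-3
(strict), exactly as conventionally quoted. Feature labels and gene
assignment use the peak **midpoint**, strand-matched, because CLIP peaks
have ragged edges and eCLIP is stranded; a peak whose midpoint falls in
two same-strand genes is assigned to both (no longest-transcript
tie-break), so bound-gene counts upper-bound a unique-assignment count.
Feature precedence is CDS-exon > 3'UTR > 5'UTR > intron > intergenic
across all overlapping transcripts; the published percentages are
disjoint, which requires *some* precedence, and coding exons are the most
specific annotation. When an annotation carries no CDS features at all,
exonic midpoints are labelled CDS-exon.

## The RNA splicing map

Each (peak, exon) pair on the same contig and strand contributes one
count — a binding *event* is a peak, counted once by its midpoint — to a
meta-exon axis: upstream flank bins, one collapsed exon-body bin, and
downstream flank bins (bin width 50 nt; half-window 2000 nt for the wide
map, 300 nt for the fine map). Orientation is transcriptional, so the
genomic side flips on the minus strand. Distances are measured 1-based
from the exon boundary on both strands; the signed display position
follows the boundary-difference convention (a midpoint 25 nt past the
exon end is +25). In-exon peaks sit in the dedicated exon bin and are
excluded from flank tests.

The null is a bootstrap over **exons**, not peaks: B times (default
1000), draw |sensitive set| insensitive exons with replacement and bin
the same peak set around them; λ per bin is the mean over draws, floored
at 1/B so the Poisson tail is defined when the null region is empty.
Exon-level resampling is chosen because the scientific contrast is
between exon classes; resampling peaks would break the per-gene
clustering of binding. Significance per bin is the Poisson upper tail
P(X ≥ observed | λ) with BH correction across the bins of one profile —
the smallest defensible family, since each profile is interpreted as a
unit. The flank tests treat the innermost 150 nt of each side as a single
bin and BH-adjust the four side×class tests together.

Two caveats are documented rather than hidden. First, λ is a bootstrap
*mean*, so the Poisson test ignores the (small) sampling variability of
λ and the exon-to-exon overdispersion of counts; with ≥ 100 insensitive
exons and the default background density this keeps the per-profile
false-positive bin fraction at or below the nominal 5% on average, but
individual seeds can exceed it. Second, when the null region truly has
zero peaks, λ sits at the 1/B floor and a single observed peak is
declared significant — with sparse backgrounds the floor is doing the
work, which is why the simulated background density defaults to a
realistic ~0.5 peaks per exon.

For MXE events the 1st exon (transcript order) takes the class given by
the ΔPSI sign and the 2nd exon the complementary class, yielding four
profiles; each is tested against the same insensitive-exon null.

## Direct targets

Direct targets are the intersection of bound genes (midpoint assignment)
and significantly spliced genes, with all significant events in those
genes tallied by type. Per-event peak counts are reported for the
upstream intron, downstream intron, and regulated exon, bounded by the
nearest flanking exon on each side (for MXE, the other alternative exon
bounds the inner intron). A peak may count for several overlapping
events — the geometries genuinely overlap — but never twice within one
event.

## The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions the package is validated under:

* 200 genes of 5–8 exons (90–250 nt) with introns of 700–1500 nt on both
  strands; introns must be at least twice the fine-map half-window so
  flank windows never collide with neighbouring exons (validated at
  config time).
* One cassette exon per gene; 10% of genes instead carry an adjacent MXE
  pair. 25% of events are sensitive, half included / half skipped, with
  |ΔPSI| = 0.4.
* GCATG is written into the designated 150-nt regulatory flank
  (downstream of included, upstream of skipped exons; configurable via
  `plant_classes`) with probability 0.5 per flank; background sequence is
  i.i.d. uniform, so chance occurrences arise at 4^-5 per nt.
* Peaks: width ~ Normal(91, 15) truncated at 30 nt, centered on motifs
  with small jitter, detected with probability 0.8; background peaks at
  ~3 per gene (~0.5 per exon) uniformly within gene spans. Motif-driven
  peaks draw stringent-passing fold enrichment and p-values; 20% of
  background peaks are drawn to fail the stringent filter, exercising
  that code path (in input-normalized CLIP data the consensus-motif sites
  are the high-enrichment class).
* Junction counts: per replicate (4 per condition), PSI is drawn around
  the class mean (conditions differ by the planted ΔPSI, replicate noise
  SD 0.01) and IJC ~ Binomial(coverage = 100, PSI). The per-event p-value
  is a pooled two-proportion chi-square test with BH correction — a
  deliberate, clearly-labelled stand-in for the splicing engine's
  likelihood machinery, adequate for generating realistic significance
  structure but never to be compared numerically against a real caller.

What passing tests show: the filters, counting, binomial/Poisson tails,
bootstrap, and intersections are correct on data whose truth is known,
the planted element and flank geometry are recovered at realistic effect
sizes, and the statistics are calibrated when nothing is planted. What
they do not show: robustness to real-data features the generator omits —
non-uniform base composition and repeats, overlapping genes and
alternative transcript structures, coverage-dependent PSI noise,
crosslink-biased peak shapes, or annotation errors.

## Numerical and edge-case policy

* Internal coordinates are 0-based half-open everywhere; GTF is converted
  at the boundary, rMATS coordinates are used as published (already
  0-based half-open), BED is native.
* Flanks truncated at contig ends are returned with a `truncated` flag
  rather than erroring — terminal exons exist in any annotation.
* `U` is normalized to `T` on input; results are reported in the DNA
  alphabet with `as_rna_kmer()` for display.
* Ties in k-mer ranking are broken by adjusted p, then decreasing
  enrichment; remaining ties are left in alphabetical order.
* Determinism: every stochastic step (generator, bootstrap, shuffle)
  runs under a caller-supplied seed via `withr::with_seed`, and
  `run_pipeline()` writes byte-identical `report.json` for identical
  config and seed.
* Test problem sizes: unit tests run 40–60-gene simulations; the
  acceptance suite uses the full 200-gene conditions with B = 1000 and
  20 seeds for the calibration and recovery checks, and B = 100–200 for
  determinism checks where the statistic's value is not under test.

## Known limitations

* The feature-precedence rule and midpoint assignment are defensible
  defaults, not reconstructions of any particular published pipeline;
  percentages shift by a point or two under any-overlap assignment.
* BH families are per profile (bins) and per flank-test quartet; a
  study-wide family across many profiles would need an explicit choice.
* The Poisson-on-bootstrap-mean approximation is slightly
  anticonservative under strong per-gene peak clustering; a
  negative-binomial extension would be the next step if real data showed
  overdispersed nulls.
* Exact-coordinate event matching across datasets requires a shared
  genome build; no liftover is attempted.
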