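---
title: "Methods: variant ranking and deletion calling for targeted gene panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant ranking and deletion calling for targeted gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paneldx)
library(dplyr)
```

paneldx implements the analysis side of a targeted gene-panel diagnostic
workflow for heterogeneous Mendelian disease cohorts, of the kind used for
neuromuscular disorders (NMD), where a few hundred known disease genes
spanning ~16 clinical classes are captured and sequenced per patient. The
package takes over after alignment and pileup: it filters raw variant
evidence, scores and ranks candidates, matches them against disease class
and segregation, and calls multi-exon deletions from window read counts.
Everything upstream of the pileup (base calling, alignment, duplicate
removal) and everything downstream of the shortlist (Sanger confirmation,
clinical interpretation) is out of scope.

## Panel construction

Capture targets are built from gene models as all coding exons extended by
`flank_nt` intronic nucleotides on each side, so that intron–exon
boundaries and nearby splice-relevant sequence are always covered; UTRs
and deep introns are excluded by construction. The classical design rule
is "at least 50 intronic nucleotides"; the exact per-exon flank used in
any given assay is a design choice, so the default is exactly 50 and it is
configurable. Overlapping contributions merge, all coordinates are
BED-style 0-based half-open, and repeat regions can be subtracted via an
externally computed exclusion table (repeat detection itself is external
tooling).

## Variant validity, zygosity, and the false-positive flag

Every decision boundary is applied exactly as quoted in diagnostic
practice, with strictness preserved:

| rule | boundary | strictness |
|---|---|---|
| valid variant | seen on both strands | ≥ 1 read each |
| coverage floor | depth ≥ 3 | inclusive |
| quality floors | MAPQ 25, consensus 20, SNV/indel 20 | inclusive |
| homozygous call | alt fraction > 0.80 | strict |
| probable false positive | alt fraction < 25% or alt reads < 8 | strict |

The coverage floor applies to total depth, not alt-supporting depth. On
chrX, a homozygous-fraction call in a male is reported as hemizygous;
pseudoautosomal regions are not special-cased because their handling is
panel-dependent. The false-positive flag annotates candidates for
orthogonal confirmation but never deletes them. Known benign variants
(population-database polymorphisms) are removed unless annotated
pathogenic or probably pathogenic — healthy carriers place true recessive
mutations in population databases, so clinical significance always wins.

## Scoring and ranking

Categories are ranked in the canonical severity order: nonsense,
frameshift, essential splice, start loss, stop loss, missense, predicted
splice, in-frame indel, synonymous. Only this *ordering* is prescribed;
the integer base scores (100, 95, 90, 80, 75, 50, 45, 30, 10) are package
defaults, config-exposed, and any strictly decreasing assignment satisfies
the ordering invariant. Modulation is additive rather than
multiplicative: +5 for strong conservation (phastCons ≥ 0.95), +5 each for
SIFT-damaging (< 0.05) and PolyPhen-damaging (≥ 0.85) missense calls, +20
for synonymous or predicted-splice variants whose relative splice-score
loss reaches 0.10. Additive composition keeps the compound-heterozygote
sum rule well defined and auditable. Variants with pathogenic clinical
significance receive +200, which the config constructor verifies exceeds
any achievable unweighted score, so known mutations always surface.
Missing annotations contribute nothing — scores may be absent but never
silently zero.

Under recessive segregation, per-gene evidence is the best valid allele
pair: a homozygous or hemizygous variant counts twice (a single homozygous
nonsense must outrank a lone het of the same category, since it alone
completes a recessive diagnosis), and otherwise the two highest-scoring
heterozygous variants are added. Exactly two are added — two alleles cause
a recessive disease; further hets are treated as noise. Candidates in
genes outside the patient's disease classes are demoted to a secondary
list rather than deleted, because informative variants do turn up outside
a strict class match. Ties break lexicographically (gene, chromosome,
position) for reproducibility. Read-backed phasing (detecting that two
"compound het" changes are actually in cis from shared fragments) is not
implemented; such pairs rank as compound heterozygotes and need manual
review.

The splice scorer is pluggable: any function mapping a 9-nt donor or
23-nt acceptor context to a non-negative score can be supplied, and the
reported effect is the maximum relative loss across scorers. The bundled
default is a position-weight-matrix scorer built from classical mammalian
consensus frequencies (normalized geometric mean with pseudocount 0.001, so
a consensus site scores 1 and disrupting an invariant GT/AG position
collapses the score). Re-implementations of the external splice tools are
deliberately out of scope.

## Deletion calling

Coverage is summarized as read-start counts in consecutive 20-nt windows
tiling the capture targets. A test sample is compared against exactly
three reference samples (subsampled with a seeded RNG when more are
available): per window, the library-size-normalized ratio
test/median(references) is formed, and informative windows (reference
median raw count ≥ 10) with ratio ≤ 0.15 are loss windows. Runs of ≥ 5
loss windows (merging runs separated by < 3 windows) overlapping a target
become calls. The window size and three-reference comparison follow the
published design; the ratio threshold, informativeness floor, and run
lengths are package defaults validated by simulation — a hemizygous or
homozygous loss has ratio ≈ 0, so any threshold well below 0.5 detects it
and the run-length floor suppresses single-window capture noise.
Heterozygous single-copy autosomal losses (ratio ≈ 0.5) are not called by
default; the thresholds are exposed for experimentation.

Breakpoints are conservatively bracketed by the window grid and then
narrowed with off-target reads: the sparse reads that capture leaks into
flanking introns bound the true breakpoint much more tightly than the
exon-limited grid. Refinement never widens an interval. Sex is inferred
from the mean chrX / mean autosome window-count ratio (male in (0.3, 0.7],
female in (0.7, 1.3], otherwise unclassified), or against a known-female
reference profile.

## The simulator

The synthetic-data generator emulates the pipeline's inputs at pileup and
window-count granularity — deliberately not at read level, since the
pipeline consumes post-alignment evidence. Defaults mirror the study
conditions of a multiplexed diagnostic run: mean depth 138 reads, window
size 20 nt, flank 50 nt, four-sample cohorts, and a negative-binomial
depth model with size 25, reflecting the narrow per-exon coverage spread
of reproducible capture experiments (95th percentile close to the
median). Males get half depth on chrX; an implanted deletion zeroes the
windows of its exons, removes overlapping variants, and excludes
off-target reads from the deleted interval while recording the exact
simulated breakpoints in the truth manifest. Decoy variants are
benign-like (synonymous/missense with sub-threshold annotation scores,
~20% listed as known polymorphisms, a sliver with deliberately failing
strand or quality evidence so the filters have work to do). The optional
GC effect applies a monotone-decreasing multiplier to window coverage,
emulating the GC–coverage anticorrelation qualitatively, not fitted to any
instrument.

What passing tests on this simulator do *not* show: robustness to
alignment artifacts, capture-efficiency heterogeneity between targets,
indel realignment ambiguity, or pseudogene cross-mapping — all real-data
phenomena upstream of this package's contract.

## Verification problem sizes

The test suite and acceptance script run entirely on simulated cohorts
chosen to be decisive yet quick: 30-gene panels with ~140 decoy variants
for archetype-recovery runs (five mutation archetypes — het frameshift
X-linked carrier, homozygous nonsense recessive, hemizygous intronic
splice, het missense dominant, compound het recessive — each ranked first
among > 100 decoys); twenty seeded cohorts with deletions of 2–40 exons at
depths 50–200× for deletion-recovery (recall 1.0, edges within one
window); and a 79-exon X-linked gene with exons 18–44 deleted for the
worked dystrophin-geometry example (27 affected targets, mean deleted
window count 0, off-target reads bracketing the breakpoints). Determinism
is part of the contract: every stochastic step is seeded and the simulator
is byte-identical under a fixed seed.

## Known limitations

Duplications and copy-number gains are not called; phasing is not
performed; consequence categories are consumed as input, not predicted
from transcript sequence; and the bundled splice PWM is a deliberately
simple stand-in for dedicated splice-prediction tooling, adequate for
ranking relative loss but not for clinical splice interpretation.
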