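---
title: "Remapping enhancer-promoter interactions across genomes: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Remapping enhancer-promoter interactions across genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntenicLRI)
```

## The procedure

The pipeline carries chromatin interactions detected in one species onto
the genome of another and asks two questions: *is the interaction
syntenically conserved*, and *does the remapped region behave like a
regulatory element in the target species*?

**Source-side preparation.** Interaction anchors are classified against
gene models: *promoter* when the anchor overlaps (≥ 1 bp) a window of
±2.5 kb around any TSS, otherwise *genic* when it overlaps a gene body,
otherwise *intergenic*. Only promoter ↔ non-promoter pairs are kept,
normalized promoter-first. Each non-promoter anchor is then called
*active* (qualifying H3K4me1 and H3K27Ac peaks that also overlap each
other by ≥ 10 bp), *poised* (qualifying H3K4me1 only), or *none*
(excluded). A peak qualifies if, after merging abutting/overlapping peaks
of the same mark, it is ≥ 300 bp long and touches the anchor. Replicates
are pooled, with provenance retained in the replicate-prefixed id.

Two readings of the "10 bp minimum reciprocal overlap" clause are
possible: mark↔mark or mark↔anchor. We implement mark↔mark — the active
state is evidence that the *same* stretch of DNA carries both
modifications — and keep mark↔anchor contact at ≥ 1 bp. The merge
pre-pass exists because without it the state call would depend on how a
peak caller happened to fragment a region, violating the invariance (test
suite: splitting a peak into abutting pieces never changes the call).

**Liftover.** The remapping engine implements the classic chain-file
contract. Among the chains whose source span overlaps the query interval,
the highest-scoring one is selected (ties broken by lower chain id) — the
single-best-chain rule mirrors default liftOver behaviour; a multi-chain
union would inflate the mapped fraction. The *mapped fraction* is the
share of query bases inside aligned blocks; at fraction ≥ `min_match`
(default 0.5) the result is the enclosing span of the mapped bases,
reported as one forward-strand interval even for reverse-strand chains
(reflection `p' = size − p`), because all downstream overlap logic is
strandless. The flag semantics of minMatch 0.5 make the comparison `≥`;
we follow the flag rather than the looser prose "more than 50%" — at
exactly 50% mapped bases the interval maps.

**Synteny classes.** Promoter and enhancer outcomes combine into five
classes (`P_plus_E`, `split`, `E_only`, `P_only`, `lost`) that always
partition the input — overall and within each enhancer state. Redundancy
among `P_plus_E` records is flagged when *both* the promoter and the
enhancer intervals of two records reciprocally overlap by more than 50%
of each interval's length; groups are connected components of that
relation. We chose the reciprocal reading (not one-sided sharing) as the
conservative interpretation: one-sided linking would let a long interval
absorb many short ones. Remapped regions are annotated with the priority
promoter > exonic > intronic > intergenic, and a `P_plus_E` record is
flagged as spanning multiple genes when a complete third gene lies
between its anchors or its enhancer is intragenic to a gene other than
the promoter's.

**Concordance.** A remapped enhancer *matches* a tissue's histone layer
at ≥ 50 bp overlap; coverage fraction is overlap bp / enhancer length.
The cumulative curve adds tissues in ascending order of matched count and
reports unique-union sizes. TAD status is *intra* when one TAD fully
contains both anchors (strictest reading of "located within"; midpoint
rules would silently pass anchors that straddle boundaries), *inter* when
each anchor is inside some TAD but none holds both, *outside* otherwise.
A record is represented in a loop dataset when one loop's anchors overlap
its promoter and enhancer respectively, in either orientation, at ≥ 1 bp
(the permissive default; the threshold is a config knob since published
loop calls have heterogeneous resolution). Conservation is summarized per
region as the mean per-base track score — the simplest summary, chosen
because no particular statistic is canonical — and compared to
length-and-chromosome-matched shuffled regions by a two-sided Wilcoxon
rank-sum test (`stats::wilcox.test`: exact for small untied samples,
normal approximation with continuity and tie corrections otherwise). The
shuffled null matches length and chromosome only; we did not implement
GC matching because the generator plants no GC structure and the
methodological definition of the null is length + chromosomal
distribution.

**Disease overlays.** Variants are filtered at PPA strictly > 0.01
(1-based positions; position *p* is inside `[start, end)` iff
`start ≤ p−1 < end`) and intersected with remapped enhancers; hits
inherit the connected gene from the interaction's promoter annotation.
Binding-site disruption is scored as a best-window log-odds delta: every
placement of the motif window covering the variant, on both strands, is
scored as `Σ log2((p_base + 0.01)/0.25)` bits for the reference and
alternate alleles; `lost` when the best-alt minus best-ref delta is
≤ −1 bit, `gained` at ≥ +1. This is a deliberate simplification of
full motif-disruption machinery: the pipeline only needs lost/gained
calls, and the exhaustive-window delta is auditable against a brute-force
oracle to 1e-9. CNV enrichment uses a CNV-level hypergeometric layout
(universe = all CNVs of both cohorts, successes = CNVs hitting any
interaction anchor, draws = the case cohort) — the 2×2 is not uniquely
determined by the prose of cohort comparison, and the CNV-level layout is
well-posed and exchangeable under the null, which the calibration test
verifies directly. Enhancer-only disruptions keep CNVs hitting an
enhancer but not the promoter *of the same interaction*, with a
`case_exclusive` flag when no same-type control CNV mirrors the case CNV
at ≥ 50% reciprocal overlap. Pathogenicity classes are carried from the
input annotation, never computed.

## The synthetic world

`build_world()` constructs a source genome of 50 kb interaction slots and
derives the target genome by a recorded script of block copies, an
inversion (half of the both-anchor slots map through a reverse-strand
chain), translocations (split slots send their promoter and enhancer
halves to different target chromosomes) and deletions. Deletions are
realized as *chain gaps*, not absent chains, so partial-overlap fractions
are well defined and the minMatch logic is genuinely exercised: the
failing anchor of an `E_only`/`P_only` slot keeps exactly 40% of its
bases aligned. The emitted chain file exactly describes the
rearrangement; coordinates follow BED (0-based half-open) and UCSC chain
conventions, including reverse-strand target coordinates counted from the
chromosome end.

Defaults were fixed once as the study conditions: 10 interactions per
class; 2 kb anchors ~18 kb apart (ChIA-PET-typical anchor sizes and
contact distances); PET counts 2–40; two-thirds active enhancers; four
target tissue layers with H3K4me1 match fractions 0.90/0.94/0.80/0.85
(inside the empirically typical 80–94% band) and H3K27Ac for two of
them; two loop datasets at 30% coverage with 50% redundancy (union 45%);
one TAD dataset covering every interaction and one with an 80/10/10
intra/inter/outside mix; conservation 0.9 on remapped enhancers over a
0.1 background; 5 in-enhancer risk variants (three of them planted to
disrupt or create a near-consensus 8-mer motif), 3 below the PPA cutoff,
5 in background DNA; cCREs over 95.5% of source enhancers; CNV cohorts
of 500 cases and 500 controls at a control hit rate of 0.30 and case
odds ratio 5 (odds `p1/(1−p1) = OR · p0/(1−p0)`), with the realized 2×2
recorded.

What the generator does *not* emulate: realistic nucleotide composition
or GC structure (target sequence is uniform random except at planted
motifs), peak-caller noise, read-level data, biologically realistic
rearrangement size spectra, or interactions that interfere with one
another (each slot is independent). Passing tests therefore demonstrate
the correctness of the coordinate arithmetic, classification logic and
statistical calibration — not robustness to the messiness of real peak
and loop calls.

## Numerical choices and degenerate inputs

* Chain parsing validates block arithmetic exactly (sums of sizes and
  gaps must reproduce the header spans) and rejects violations naming the
  chain id.
* Liftover ties on chain score break by lower chain id; mapped fraction
  is invariant to chain list order.
* The Wilcoxon comparison short-circuits to p = 1 when both score vectors
  are a single identical constant (the test is uninformative).
* Hypergeometric enrichment returns p = 1 with a logged note on
  degenerate margins (K = 0 or K = N).
* `shuffle_regions` errors when a region is longer than its chromosome;
  a region exactly as long as its chromosome has one forced placement.
* Variants whose reference allele disagrees with the genome sequence are
  an error naming the position, not a silent skip.
* Cumulative-match ties between tissues with equal counts are broken by
  tissue name, making the curve deterministic.

## Problem sizes used by the test suite

The suite runs the generator's default world (50 interactions), 100
seeded rebuilds for truth recovery, a 10,000-interval liftover battery
against a per-base brute-force oracle, 500 cohort replantings for the
null calibration of the enrichment test, 200 seeded placements for the
conservation null, and 1,000 random (sequence, PWM, variant) triples for
the motif scorer. These sizes give tight Monte-Carlo control while
keeping a full run in a few minutes on one CPU.

## Known limitations

* The liftover reports one enclosing span per anchor, not split
  fragments; anchors that map to two distant regions of one chromosome
  are summarized by their span.
* Single-best-chain selection means an anchor never maps to two
  chromosomes at once; the `split` class arises only between the two
  anchors of a pair.
* The motif scorer is a log-odds best-window delta, not a full
  motif-disruption model with per-motif score distributions.
* Real chain files may contain overlapping chains of similar score where
  best-chain selection is fragile; the generator plants unambiguous
  chains, so this regime is untested against real data.
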