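---
title: "In-silico 35S rDNA profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico 35S rDNA profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnaprof)
```

## The biological problem

Eukaryotic 35S rDNA is organized as long tandem arrays of a repeated unit:
18S rRNA gene, internal transcribed spacer 1 (ITS1), 5.8S gene, ITS2, 25S
gene, and the intergenic spacer (IGS). In an allopolyploid, two homoeologous
unit families coexist — one inherited from each progenitor — and three
questions arise that short-read data can answer without blots: how many
units per 1C genome, how heterogeneous the units are within a genome, and
in what ratio the two parental families are present (and expressed, via the
diagnostic CAPS assay). This package implements that read-based workflow,
together with a synthetic array/read generator so that every estimator can
be validated against planted truth.

## Copy number from the genome proportion

The estimator assumes reads sample the genome uniformly, so the fraction of
reads mapping to an rDNA reference estimates the genomic fraction occupied
by that family. Using the conserved 1.81-kb 18S gene as the reference
avoids length differences between the families. With `m` of `T` reads
mapped, GP = 100 m/T (%), GS = G × GP/100 (Mb, G the 1C size in Mb,
converted from pg at 978 Mb/pg), and copies per 1C = GS/0.00181 Mb. The
chain is computed on unrounded intermediates and rounded
(half-away-from-zero) only at the end; this matters — pre-rounding GP to
two decimals shifts the copy number of a 620-Mb-genome configuration by
about five units — so reports state the convention explicitly. Assumptions
the estimator does not model: GC/mappability bias and coverage dispersion;
in libraries where these are strong the GP is biased accordingly.

## Read preparation and the mapper

Trimming is the modified-Mott rule: each base scores
`quality_limit − p_err` (default limit `0.05`, an error probability) and
the retained segment is the maximum-sum contiguous substring, the leftmost
(then shortest) among equal scorers; a read with no positive-scoring
substring trims to empty. The ambiguity (any `N`) and minimum-length
filters (100 nt for 100-nt libraries, 150 for 150-nt ones) are applied
after trimming, which is the stricter and more reproducible order.

The aligner is a compiled local ("glocal") dynamic program with the cost
model mismatch 2, insertion 3, deletion 3, and match reward +1: reference
flanks are free and unaligned read ends are soft-clipped. Stating the
objective as a pure cost minimization would be degenerate (an empty
alignment costs 0), so the optimum maximizes `matches − 2·mm − 3·gaps`;
the reported cost of that optimum is `2·mm + 3·ins + 3·del`. Identity is
defined as matches over aligned columns (gap columns included), and a
placement is accepted when aligned read fraction ≥ 0.5 and identity ≥ 0.8,
both inclusive. Ties resolve deterministically (smallest read end, then
smallest reference end; traceback prefers diagonal, then deletion, then
insertion). The unit reference is doubled so junction-spanning reads of the
circular tandem model align contiguously; coordinates are folded back
modulo the unit length and each read counts once. A read found verbatim in
the doubled reference short-circuits the DP, which is what keeps
error-free simulations fast.

## Variant profiling

Per position, coverage counts every accepted alignment spanning it
(including reads deleted there); a call requires coverage ≥ 300, supporting
count ≥ 30 and per-allele frequency ≥ 0.10 (high) or ≥ 0.01 (low). The
thresholds are deliberately coverage-hungry: they suppress sequencing error
at the expense of sensitivity in shallow libraries, which is appropriate
for multi-hundred-copy tandem repeats. Deletions are reported per spanned
position and insertions left-anchored; multi-nucleotide variants are
emitted as per-site calls. Windowed summaries count calls in fixed
non-overlapping 100-bp windows (`1–100`, `101–200`, …).

## Homoeologue classification

The diagnostic window is the 50-bp stretch of the positionally aligned
ITS1 pair with maximal column divergence (leftmost on ties; a warning flags
identical inputs). Fragments recruited from reads (best local alignment
covering the full window; reads with `N` discarded) are classified by the
smaller Hamming distance to the D vs S consensus — fragments whose
extraction contains indels are compared by unit-cost edit distance, gaps
counting as mismatches — with exact ties left unassigned and percentages
taken over assigned fragments. The NJ tree on Jukes–Cantor distances is
built for confirmation and visualization, not as the operational
classifier; on clean two-cluster data the two agree (a property the test
suite checks at ≥ 99%).

Phylogenetic choices: pairwise deletion for gap/ambiguity columns (window
fragments are short; complete deletion would discard too much), saturation
(p ≥ 0.75) capped at a configurable maximum distance and flagged, negative
NJ branch lengths clamped to zero and flagged, and Q-criterion ties broken
by current label order so trees are reproducible. Bootstrap resamples
alignment columns with replacement (default 100 replicates) and scores
each internal edge by bipartition recovery. Because window fragments are
equal-length and window-anchored, no progressive multiple realignment is
performed — a deliberate simplification.

`branch_assign` needs the internal edge "between" the two family
references; on the path between them the package cuts the longest internal
edge, which under the intended regime (~10% between-family vs ~1%
within-family divergence) is the family separator. Haplotype diversity is
distinct-sequence count over sample size, and the two families are
compared by a Pearson chi-square (no continuity correction) on the 2×2
table `[haplotypes, sequences − haplotypes]` per family — one concrete
choice of comparison, stated as such. Degenerate tables (a zero row or
column, e.g. all fragments unique in both families) are refused.

## Digestion, methylation and CAPS

Restriction sites are exact motif matches on one strand (the built-in
enzymes have palindromic motifs). Fragment lengths are measured between
motif start positions: in a tandem array of identical units the
start-to-start distance equals the cut-to-cut distance whatever the
enzyme's intra-motif cut offset, so offsets are not modelled. Methylation
rules: BglII insensitive; XhoI blocked iff the second C of CTCGAG is
methylated; PstI blocked iff either C of CTGCAG is. With one site per unit
blocked independently with probability `b`, fragments spanning `k` units
follow the geometric law `(1−b)b^(k−1)`; the simulator reproduces it and
the multi-site case is simulation-only. Virtual gel lanes merge bands
within 1% relative length (gel resolution); the gDNA lane pools both
homoeologue amplicons and the cDNA lane only the expressed ones. MluI is
registered methylation-insensitive: it is used here exclusively on PCR
amplicons, which carry no methylation.

## What the generator emulates — and what it does not

`rdna_templates()` builds a D-like unit of 8084 bp and an S-like unit of
9215 bp. Only the total unit and 18S lengths are externally fixed; the
other subregion defaults (ITS1 230, 5.8S 164, ITS2 220, 25S 3360, IGS
absorbing the remainder) are the package's own choices at typical grass
magnitudes, with all boundaries up to the 25S end shared between families
so homologous subregions sit at identical coordinates and the ITS1 pair is
positionally alignable. Coding regions of S are copied from D at 1%
divergence (their real conservation is what lets one 18S reference serve
both families); ITS1 diverges at 10% with one substitution forced into the
MluI motif (the CAPS polymorphism); ITS2/IGS are family-specific random
sequence. Both templates carry the BglII pair at motif starts 3850/5185 —
inside the 25S gene, spaced 1335 bp, giving the 1.3-kb/6.7-kb D fragment
pair — plus one XhoI and one PstI site; planted motifs are scrubbed from
every other position.

Unit heterogeneity is i.i.d. per-site substitution, either spacer-biased
(ITS1/ITS2/IGS only — the concerted-evolution signature, default rate
0.005/site) or uniform (pseudogene-like). Reads are wrap-around substrings
of a circular tandem unit with per-base substitution errors and constant
Phred qualities; background reads are uniform random sequence, so a read
is rDNA-derived with probability `W/(W + background_genome_size)`, making
the genome proportion controllable. Mixtures draw
`round(n_total × s_fraction)` S reads (halves away from zero) or explicit
per-family counts.

Not emulated: real progenitor sequences, indel sequencing errors (a
separate knob, off by default), quality-value variation along reads,
paired ends, bisulfite reads, and flanking/transposon genome context.
Passing tests therefore demonstrate correctness of the estimators under
substitution-dominated, uniform-coverage conditions, not robustness to
every artifact of real libraries.

## Problem sizes and numerical conventions in the shipped tests

The test suite works at deliberately reduced scale so the full suite runs
in minutes: 1-kb miniature units for mapping-heavy checks, libraries of a
few hundred to a few thousand reads, 222-fragment homoeologue samples
(the scale at which the ratio estimator is meant to operate), 50-replicate
bootstraps on ≤ 10 taxa, and 150-unit arrays over 50–60 simulated digests.
Stochastic recoveries are asserted within 3σ of the corresponding
binomial/hypergeometric law under fixed seeds; exact arithmetic (dosage
chain, digestion lengths, window selection) is asserted to equality.
Floating-point threshold comparisons use a 1e-9 tolerance so that
boundary cases (identity exactly 0.8, frequency exactly 1%) are inclusive
as specified.

## Known limitations

* The aligner is exact but O(read × reference) per read; it is sized for
  unit-scale references (≤ ~10 kb), not genome-scale mapping.
* GP-based copy numbers inherit library composition biases; no
  GC/mappability correction is attempted.
* The NJ/bootstrap implementation is plain R and comfortable to a few
  hundred leaves; beyond that, export the distance matrix and use a
  dedicated tree builder.
* The variant caller emits per-site events only and performs no
  strand-bias or quality-aware filtering.
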