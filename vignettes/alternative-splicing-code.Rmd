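---
title: "The alternative mRNA splicing code: model, parameters and design notes"
author: "spliceCode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The alternative mRNA splicing code: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceCode)
```

## The model

Almost every spliceosomal intron begins with a donor dinucleotide (usually
`gu`, sometimes `gc` or, in minor-spliceosome introns, `au`) and ends with an
acceptor dinucleotide (`ag` or `ac`). The hypothesis behind this package is
that the *pair* of extended boundary sequences — an intron 5' prefix and a 3'
suffix, written `donor_acceptor` such as `guaagu_ag` — carries information
about *which kind* of alternative splicing the intron participates in, in
analogy to a degenerate code.

The code has two coordinate systems:

* **Exon types.** On the transcript set of a gene, every unique exon gets one
  of seven types: retained/invariant (`R`), skipped (`S`), alternative 5' or
  3' splice site (`A5`, `A3`), mutually exclusive (`ME`), alternative
  promoter (`APr`) and alternative poly-A (`APA`).
* **Intron classes.** An intron is labeled by its flanking exon types in
  transcription order, `Xa-Xb`. Because an `APA` exon is always the last
  exon of its transcript and an `APr` exon always the first, `APA` can never
  be upstream of an intron and `APr` never downstream, leaving
  6 × 6 = 36 valid classes rather than 7² = 49.

The pipeline then (i) discovers the paired consensus motifs that at least
`minCount` introns share, (ii) assigns every intron exclusively to its most
specific motif, (iii) tests every motif for enrichment/depletion in every
class with Fisher's exact test, and (iv) uses the resulting code table to
interpret splice-site point mutations: a mutation that moves an intron from
one consensus to another predicts a shift toward the splicing events whose
classes are enriched for the new consensus.

## Exon-type rules and their tie-break

The source material names the seven types but does not define them
operationally, so the package implements the standard event taxonomy:

* `APr`/`APA`: terminal exon of some transcript in a gene with ≥ 2 distinct
  transcription start (respectively end) positions.
* `ME`: member of a non-overlapping exon pair, never co-occurring in any
  transcript, with a shared flanking exon.
* `S`: internal exon that some other transcript bridges — its two neighbors
  appear there directly joined.
* `A5`/`A3`: another exon shares the acceptor-side (donor-side) boundary but
  differs on the other side. Boundaries are taken on the transcribed strand,
  so minus-strand genes are handled after strand normalization.
* `R`: everything else.

An exon can satisfy several rules at once; one label is forced by the
precedence `APr > APA > ME > S > A5 > A3 > R` (positional types first, then
the most specific internal patterns, with `R` as the default). The
precedence is a package argument, not a constant, because the choice is
genuinely open: an exon whose both boundaries vary, for instance, is `A5`
under this order. When an exon is terminal in one transcript but internal in
another, the intron labeler resolves the conflict contextually — an upstream
flank is never `APA`, a downstream flank never `APr` — so every intron of a
filtered gene always receives one of the 36 classes. If different
transcripts hand the same genomic intron different flanking pairs, the
lexicographically smallest label is kept and a warning is raised.

## The quaternary tree and the percentile selection rule

Donor prefixes (up to `donorLen = 10` intron bases) go into a prefix tree
over `{a, c, g, u}`; acceptor suffixes (up to `acceptorLen = 10`) go into a
suffix tree indexed from the 3' end inward. Each node carries

* `count` — sequences passing through the node,
* `prob` — the conditional branch probability `count / parent count`,
* `entropy` — the Shannon entropy (bits, in [0, 2]) of the children's count
  distribution (0 for childless nodes).

Among *eligible* branches (`count >= minCount`, default 100, the cutoff used
for statistical stability), a branch is *conserved* when its probability
reaches the 95th percentile of eligible probabilities **and** its entropy is
at or below the 5th percentile of eligible entropies. Percentiles are
inverse-CDF empirical quantiles (`type = 1`), computed per tree, inclusive
at the threshold with ties kept. The deepest conserved node on each
root-to-leaf path becomes a motif. Conserved donor and acceptor motifs are
paired by Cartesian product (the pairing rule is not prescribed by the
source material; the product followed by the joint `minCount` filter is the
least-committal choice), every intron is assigned exclusively to the most
specific pair it matches (longest donor motif, then longest acceptor motif,
then lowest rank), pairs falling below `minCount` are dropped, and
assignment is iterated to a fixed point. Ranks order pairs by descending
count with lexicographic tie-break for determinism.

Two consequences of the percentile rule are worth knowing:

* Branches with probability exactly 1 and entropy exactly 0 are *always*
  selected, whatever the percentile thresholds, because the cuts are
  inclusive and 1 (resp. 0) bounds the distribution. Exactly planted motif
  families therefore cannot be missed.
* With per-base noise the chain probabilities become slightly distinct real
  numbers, and a 95th-percentile cut over an eligible set dominated by
  family chains keeps only the top sliver of nodes. Recovery of *all*
  planted families from noisy data is therefore not guaranteed by the rule
  itself; it requires background branches to fill the eligible set. The
  unit tests exercise both regimes, and the oracle-equivalence tests (a
  brute-force enumeration of every prefix/suffix) hold with and without
  noise.

Motif candidates are restricted to biologically valid cores (donors starting
`gu`/`gc`/`au`, acceptors ending `ag`/`ac`, length ≥ 2), which also discards
degenerate single-letter branches such as the root's universal `g`.

## Enrichment and the code table

For each (motif, class) cell the 2×2 table is formed over the *full* intron
universe — introns matching no consensus stay in the universe and contribute
to the complementary margins, which is what makes the rank-0 "ALL" row of
the consensus table meaningful. Both exact hypergeometric tails are
computed: `p_up = P(X >= a)` for enrichment and `p_down = P(X <= a)` for
depletion (so `p_up + p_down >= 1`, the observed cell being counted twice).
Cells with `p < 0.001` are reported, with no multiple-testing correction by
default — this matches the raw-alpha reporting convention of the source
analysis; a Benjamini–Hochberg option exists (`adjust = "BH"`) but is off by
default. The exact test is conservative under the null, which the 20-seed
null-calibration test confirms empirically (< 0.5% of cells flagged at
alpha = 0.001).

## Mutation interpretation

`IVS<intron><offset><REF>><ALT>` notation is parsed with `+1` as the first
intron base; negative offsets count from the acceptor end (an extension —
the worked examples in the source are all donor-side). The interpreter
verifies the reference base, mutates the splice sequence, re-assigns the
motif, and reports enriched classes for wild type and mutant plus their set
differences. Two outcomes matter clinically:

* a *shift* (e.g. ATP7A `IVS6+5G>A`: `guaagu_ag` → `guaa_ag`, whose only
  enriched class is S-S — double exon skipping), and
* a *fall off the table* (e.g. ATP7A `IVS6+1G>A`, `gu → au`; or LKB1
  `IVS2+1A>G`, where `guauccuu_ac` is absent from the table even though the
  donor became canonical — the U12 `au_ac` and `gu_ag` cores cannot be
  mixed). The report distinguishes "no motif" from "motif with no
  significant class", and a donor-side cryptic scan lists every position in
  the first `window` (default 100) intron bases where a donor motif occurs,
  most specific motif per position.

## U12 branch-point scan

The last `window = 60` intron bases are scanned with a log2-odds PWM; the
best window per intron is kept, the empirical (1 − 0.05) quantile of best
scores is the threshold, and ties at the threshold are kept. Per class the
observed hit count is compared with `expected = class share × total hits`.
The package ships a *documented default* PWM built from the U12 branch-point
consensus `uuccuuaac` (one-hot counts of weight 10, pseudocount 1, uniform
background) — a construction of this package, not a published matrix — and
reads user matrices in 4-column TSV or MEME-minimal format. All tests use
synthetic or constructed matrices, never the default's specific numbers as
an external truth.

## Within-gene co-occurrence

Genes are reduced to their sets of assigned motif ranks;
`value[i, j]` is the Jaccard index of ranks i and j across genes (diagonal
forced to 1). The association measure and linkage are not prescribed by the
source; Jaccard with average-linkage agglomerative clustering on
`1 − value` was chosen for symmetry and robustness, and both are arguments.
With `k = NULL` the cluster count is picked by mean silhouette width over
`k = 2..8`.

## The synthetic genome generator

`simulateGenome()` is the package's test substrate, not a fixture: gene
archetypes instantiate all seven exon types (an R chain; a skipped-exon
chain in which each internal exon is bridged by one transcript, producing
S-S introns between consecutive skippable exons; A5/A3 boundary variants
shifted by 30 bases; an ME pair; APr/APA terminal variants), on random
strands, one contig per gene. Defaults: 840 genes (~5,000 unique introns),
exons 80–160 bases, introns 90–200 bases, 15% dedicated U12-like genes.

Motif planting: rows of the motif plan name a paired consensus, a target
class, a per-intron planting probability (default 0.85) and a gene group.
Within a gene, eligible introns cycle through the group's rows, so the two
U12-like families co-occur inside their dedicated genes — the structure the
co-occurrence clustering is expected to find. Each U12-group intron also
carries the branch-point consensus 17–25 bases upstream of its 3' end.

Two generator choices were made deliberately, before any acceptance
measurement, to make planted families identifiable under the percentile
rule (see above):

* planted motifs are full window length (10 + 10 nt), so each family
  terminates in nodes with branch probability exactly 1 and child entropy
  exactly 0;
* background window interiors draw from a pyrimidine-heavy, adenine-free
  alphabet (`c/g/u` at 0.4/0.2/0.4), while every planted family carries an
  adenosine at an early position, so background sequence can never extend a
  family's deep branches and dilute its chain probabilities below 1.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: realistic splice-site degeneracy (real donors
share long fuzzy consensus gradients rather than exact 10-mers), overlapping
genes, paralogy, N runs, annotation errors beyond the structural ones the
pre-filter drops, expression levels, and any coupling between intron length
and class. Recovery results on this generator demonstrate correctness of
the machinery, not sensitivity on genomic data.

## Numerical and degenerate-input choices

* Quantiles everywhere are inverse-CDF (`type = 1`), inclusive, ties kept.
* Hypergeometric tails come from `phyper`, which is exact in double
  precision for these table sizes; genome-scale p-values such as 10⁻¹⁴ are
  far from underflow.
* Intron intervals are half-open 0-based internally at extraction time and
  surface in the 1-based closed `GRanges` convention.
* Introns shorter than `donorLen + acceptorLen` get truncated,
  non-overlapping windows (donor takes the first half, rounded up).
* Splice sequences containing ambiguous bases exclude the intron from tree
  construction (a quaternary tree has no N branch); the intron stays in the
  universe for enrichment.
* A selection with no eligible branch returns an empty motif set rather
  than an error, so thin inputs degrade gracefully.
* Rank ties in the consensus table break lexicographically; cluster and
  grid orders are fixed; the generator and pipeline are deterministic given
  their seeds.

## Problem sizes used by the test-suite and acceptance runs

The packaged checks run at desk scale, chosen to exercise every code path
with comfortable statistical margins: oracle equivalence for Fisher tails
covers every margin with a table total up to 60; tree-discovery oracle
equivalence uses mixtures of up to 500 sequences at depth 6; parameter
recovery runs 20 generator seeds at the default ~5,000-intron scale with
planting probability 0.85 (every planted family has ≥ 300 planted introns);
null calibration uses 20 × (10,000 introns × 20 motifs × 10 classes). The
printed-table fixtures (the ranked human consensus table, the code grid,
and the ATP7A/LKB1 junction sequences) cover the worked examples; the
genome-scale human numbers themselves require the human genome and are out
of scope here.

## Known limitations

* The exon-type rules are a reconstruction of a taxonomy the source defines
  only by name; corner cases (double-boundary variation, one-label forcing)
  follow the documented precedence rather than any external standard.
* The pairing of donor and acceptor trees, the percentile basis, and the
  iterated exclusive re-assignment are all documented interpretations of an
  under-specified procedure; each is parameterized so alternatives can be
  explored.
* The Table-2-style grid lists every rank passing alpha, which may be more
  verbose than a "most significant only" rendering of the same analysis.
* The ATP7A/LKB1 fixture sequences are synthetic outside the
  figure-documented junction features (see `?loadFixture`).
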