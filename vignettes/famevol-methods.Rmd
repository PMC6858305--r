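---
title: "Methods: gene-family comparative genomics with famevol"
author: "famevol maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family comparative genomics with famevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famevol)
```

## The analysis protocol

`famevol` implements a comparative genomic analysis protocol for
eutherian multi-member gene families — families like the connexins, with
roughly twenty paralogous genes per genome, curated across tens of
mammalian species. The protocol chains five stages, each of which can
also be used on its own:

1. **Reliability.** Public genome assemblies contain sequencing and
   assembly errors, and an apparently intact coding sequence may rest on
   unsupported bases. A candidate is accepted as a *complete* coding
   sequence only if read coverage reaches every one of its nucleotides;
   otherwise it is *putative* and excluded from every downstream stage.
   The unit of evidence is a per-read alignment interval (1-based,
   inclusive) on the candidate; depth is computed by interval coverage.
   Coverage here means overlap only: the protocol does not assess
   base-level agreement between read and assembly, because no agreement
   threshold is defined for it — this is documented behaviour, not an
   omission.
2. **Alignment.** Proteins are aligned (by any external aligner and/or
   hand curation — alignment production is deliberately pluggable input),
   the package verifies that each degapped aligned row equals the
   translation of its coding sequence, and back-translates into a
   codon-structured nucleotide alignment where gaps occur only in
   whole-codon units. Terminal stop codons carry no aligned residue and
   are excluded from the alignment (they still count in codon-usage
   statistics).
3. **Identity.** Pairwise nucleotide identity *a* is computed under
   pairwise deletion: columns with a gap in either row are excluded, and
   *a* = matching columns / compared columns. Pairs with zero comparable
   columns are flagged `NA` rather than silently given a value. Summary
   statistics are the mean *ā*, average absolute deviation
   *ā*~ad~ = mean |a − ā|, and extremes a~max~, a~min~, computed over
   off-diagonal pairs, each pair once.
4. **Tree.** Distances are 1 − *a* (p-distance, default) or the
   Jukes–Cantor transform −(3/4)·ln(1 − (4/3)p). Trees are built with
   neighbor joining, the canonical greedy heuristic for the
   minimum-evolution criterion. Bootstrap resamples codon columns (the
   alignment is codon structured, so the codon is the exchangeable
   unit), and each internal edge's support is the percentage of
   replicate trees containing its bipartition.
5. **Protein molecular evolution.** Codon counts pooled over the whole
   data set give, per standard-code synonymous family, expected counts
   under uniform usage (family total / family size) and the relative
   synonymous codon usage ratio *R* = observed / expected. Codons with
   *R* ≤ 0.7 (inclusive) form the *not preferable* set. Each reference
   residue's alignment column is then classified: *invariant* if all
   non-gap amino acids agree, otherwise *forward* if no codon in the
   column is not-preferable, otherwise *compensatory*. Cysteine
   landmarks, N-x-[ST] sequons and membrane-topology regions annotate
   the same alignment.

## Statistical conventions and thresholds

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| depth threshold (reliability) | 1 | reads | "supported at every nucleotide"; configurable for stress tests |
| homologue bands | 0.15/0.25/0.35/0.5 | identity | field-standard bands for eutherian homologues; half-open, lower bound inclusive, so classification is total and deterministic |
| conserved-region window | 100 | alignment columns (bp) | standard window for genomic conservation screens |
| conserved-region threshold | 95 | % identity per window | strictest cut-off, used for closely related genomes; 60% reproduces the relaxed cut-off used for divergent paralogues |
| RSCU threshold | 0.7 | ratio | inclusive cut-off defining not-preferable codons |
| bootstrap replicates | 1000 | replicates | conventional; supports below 50% are suppressed in rendered trees but always retained in data |
| duplication-timing margin | 0 | identity | raw comparison of paralogue vs orthologue identity; a margin can be set to demand a separation before calling a verdict |
| `min_calculated` (site classification) | 2 | sequences | a column where only the reference is non-gap is still classified but flagged |

Identity values are computed at full precision and rounded to three
decimals only for reporting. Identities in this package derive from the
*multiple* alignment under pairwise deletion, not from per-pair
realignments; when comparing against numbers computed with other
tooling, the alignment in use must be stated alongside.

Three genuinely open conventions were fixed as follows, with reasons:

- **Amino-acid-level invariance.** A column whose variation is purely
  synonymous (e.g. GAG/GAA) is *invariant*: the sites being classified
  are amino acid sites. Codon content only separates forward from
  compensatory among the variant columns.
- **Sequon motif.** N-x-[ST] is applied literally; the common refinement
  x ≠ P is available (`exclude_proline_x`) but off by default.
- **"Common" landmarks.** A cysteine column or sequon column is common
  to a cluster when every *non-gap* row carries it; rows gapped at the
  column do not veto.

## Distance-model substitution

Some tree programs compute a maximum-composite-likelihood distance. That
estimator's internals are not reimplemented here; `famevol` offers
p-distance and Jukes–Cantor instead, and discloses the substitution in
its run reports. Cluster-level classification — the level at which trees
are interpreted in this protocol — is robust to this choice, but exact
reproduction of a specific published tree figure (its topology and
printed bootstrap values) is explicitly not claimed: published family
trees additionally rest on hand-curated alignments. Jukes–Cantor is
undefined at p ≥ 0.75; saturated pairs are flagged, fall back to the
p-distance, and trigger a warning.

Neighbor joining can estimate negative branch lengths; they are clamped
to zero. Tie-breaking inside the NJ agglomeration is delegated to the
`ape` implementation, which is deterministic for a fixed input, so runs
are reproducible.

## What the simulator emulates — and what it does not

`simulateFamily()` exists so that every stage has inputs with known
truth. Its defaults are sized to the shape of a curated eutherian family
data set: 35 species, 21 clusters, 327 codons per sequence, four
clusters carrying duplications. Sequences evolve by per-codon-site
substitution events (Poisson along each branch); each event is
synonymous or amino-acid-changing with a single nonsynonymous-proportion
parameter, synonymous choices follow a biased codon-weight vector
(GC-ending codons favoured, as in mammalian coding sequence), and rates
are multiplied per membrane-topology region — extracellular slowest,
transmembrane intermediate, cytoplasmic fastest — reproducing the
conservation gradient the analyses assume. Designated invariant columns
(six signature cysteines arranged in the canonical `C-x(6)-C-x(3)-C` /
`C-x(4)-C-x(5)-C` spacings, two sequons, and a handful of scattered
positions) are never substituted.

Cluster structure comes from a two-level tree: each cluster's ancestor
diverges from the family root by its own depth (depths spread over
0.5–3 substitutions per codon site, producing between-cluster identities
across the homologue bands), and every cluster then evolves along one
shared coalescent species tree of height 0.5. With these defaults the
realized identities land at roughly 0.55–1.0 within clusters and
0.31–0.57 between clusters.

Two realism limits matter when reading test results:

- **No indel evolution.** Real alignments of distant paralogues contain
  long gapped stretches, which drive compared-column identities far
  below the random-matching baseline (values as low as ~0.04 occur in
  real family data sets). Without indels, between-cluster identity
  saturates near ~0.31 here, so the *very distant* band (< 0.15) is not
  produced by the generator; band logic is instead tested directly on
  constructed values.
- **No rate heterogeneity beyond regions**, no codon-model (GY94-style)
  fidelity, no alignment error. Passing the recovery tests therefore
  shows the analysis machinery is correct and well calibrated on clean,
  band-structured data; it does not certify performance on hand-curated
  real alignments.

Duplications of type *predates* split a cluster ancestor before the
species-tree root and place the second copy in a small subset of
species; *postdates* duplicates one species' gene near the tips. The
timing verdict compares within-species paralogue identity against
cross-species orthologue identity, exactly as the analysis stage does.

`simulateReadCoverage()` places reads uniformly with clipping at the
candidate ends (so coverage is uniform over the whole candidate, as with
local read alignments), and rejects any read overlapping a designated
dropout interval — dropout positions are uncovered by construction, and
the emitted truth is "complete" only when no dropout was requested and
the realized coverage has no gaps.

## Validation design and problem sizes

The test suite pairs every operation with an independent oracle: a
brute-force per-pair identity recomputation (alignments up to 10 × 30),
the naive O(L·W) sliding-window scan, exhaustive interval-union coverage
(lengths ≤ 50), an enumeration oracle for motif matching, exact NJ
recovery on additive matrices (≤ 8 taxa, distances from random trees),
and an exhaustive-topology ordinary-least-squares tree-length oracle on
5 taxa. End-to-end recovery runs at the full dataset shape
(35 × 21 × 327, ~745 records): cluster monophyly, invariant-column
recall, duplication-timing verdicts and completeness verdicts are all
checked against generator truth; a dataset-shaped run completes in a few
seconds, and the whole suite in about half a minute on one core. The
`scripts/acceptance.R` report recomputes the same quantities from
scratch under a caller-supplied seed.

## Known limitations

- Region statistics require a region map; the shipped
  `connexin_region_map_approx.tsv` is an explicit synthetic
  approximation of connexin topology for a 273-residue reference, good
  for demonstrations and structure-shaped simulations, not for
  publication-grade region statistics on real data.
- The reliability stage consumes interval tables; it does not query
  read archives or perform read alignment itself.
- The motif grammar is the PROSITE subset actually used by the analyses
  (literals, sets, `x`, `x(n)`, `x(n,m)`); anchors and excluded sets are
  not implemented.
- Identity-based duplication timing is a two-value comparison; it does
  not model rate variation between paralogues, so verdicts near the
  margin should be read as *indeterminate* by setting a positive margin.
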