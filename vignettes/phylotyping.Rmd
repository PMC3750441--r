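---
title: "Marker screening and strain typing for organelle genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker screening and strain typing for organelle genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organphylo)
```

## The model and its assumptions

`organphylo` addresses a concrete situation in microalgal systematics:
several complete plastid and mitochondrial genomes of closely related
strains are in hand, and the task is to decide *which* regions of those
genomes to use as phylogenetic markers at three resolutions — between
species in a genus, between conspecific strains, and between individual
isolates. Rather than trusting conventional barcodes, every genic and
intergenic region is extracted and measured.

Three assumptions underlie the design, all reasonable for organelle genomes
of a compact genus:

* **Collinearity.** Gene content and order are conserved, so orthology can
  be established by locus name and whole genomes can be aligned as broadly
  collinear sequences. Rearranged genomes violate this and are out of
  scope.
* **Near-identity.** Sequence divergence between the strains is a few
  percent at most, so a center-star progressive alignment (every member
  aligned to the medoid, gaps merged once-a-gap-always-a-gap) is adequate
  and fast; the package makes no claim to general-purpose multiple
  alignment quality.
* **Small strain sets.** With 4–9 strains, maximum parsimony can enumerate
  all (2n−5)!! unrooted topologies, so "the marker's tree is consistent
  with the reference" can be decided exactly, without arbitrary tie-breaks:
  a marker is consistent when the reference topology attains the minimum
  Fitch score among all enumerated topologies (ties allowed), and
  inconsistent whenever the search would have to fall back to the NNI
  heuristic. A region with no signal at all — every topology optimal — is
  never called consistent.

## The three indices of the screen

**Sensitivity** is the percent nucleotide difference of the region's
alignment. Published tables of this kind do not state whether that means
the proportion of polymorphic columns or the mean pairwise p-distance; both
are implemented (`percent_difference(aln, method =)`) and the polymorphic
-column proportion is the default, because it matches how SNP densities are
usually quoted. The choice only matters for regions with very uneven
pairwise divergences.

**Specificity** is the arithmetic mean of bootstrap supports over the
internal splits of the region's own MP tree (leaf edges excluded). The
bootstrap resamples alignment columns; because column resampling only
reweights site patterns, the per-topology, per-pattern Fitch counts are
precomputed once and each of the `B` replicates reduces to a matrix-vector
product, which keeps an exhaustive MP bootstrap cheap. `B` defaults to 100;
replicates are reproducible from the seed and invariant to row order.

**Tree similarity** is quantified as the Euclidean distance between the
region's p-distance matrix and the reference's, restricted to common
strains (an option divides by the number of pairs before the square root).
Tree-derived nodal matrices would be an alternative reading; the p-distance
form is the default because it is defined even where bootstrap trees are
poorly resolved. For the same reason the printed distances in published
tables are treated as illustrative, not as targets.

The reference itself is the exhaustive MP tree of the concatenated
protein-coding genes, with its p-distance matrix taken from the same
concatenation. Markers covering fewer strains are compared on the common
subset, and consistency then requires the restricted reference topology to
be optimal.

## Intraspecies loci and strain identifiers

Between two conspecific genomes the variation is too sparse for any single
gene, so the package scans a whole-genome pairwise alignment (unique shared
21-mers chained by longest increasing subsequence; inter-anchor gaps closed
with affine Needleman–Wunsch, match +1, mismatch −1, gap open −4, gap
extend −1 — defaults chosen for near-identical sequences and overridable)
with a 500-site window stepped by 25 sites. Windows with at least 6
segregating sites are merged into variable regions. `S` excludes gap
columns, following the segregating-sites convention of DnaSP-style scans;
indel alleles are retained as genotype characters during typing but do not
count toward `S` during discovery. Each merged region is reported as the
span from its first to its last variant position — the way MLST loci are
tabulated — while the surrounding merged-window interval, whose flanks lie
in background-rate sequence, provides the anchors (25 bp, up to 2
mismatches tolerated) used to recover the locus from further strains.

Perfect microsatellites are detected as maximal runs of primitive 1–6 nt
motifs, canonicalized to the lexicographically smallest rotation, with
minimum total lengths of 10 nt (mono, di) and 12 nt (tri–hexa). These
thresholds are inferred from the shortest loci that published panels of
this kind report (a 10 nt poly-A); the tools behind those panels are
unnamed, so the thresholds are configurable. Imperfect or compound repeats
are out of scope. Circular genomes are scanned on the doubled sequence and
origin-crossing loci deduplicated.

## Ka/Ks

`ng86()` implements the classic Nei–Gojobori method: per-codon synonymous
site fractions with mutations to stop codons excluded from the
denominators, equal-weight averaging over all minimal mutational pathways
between differing codons (pathways through stops discarded, codon pairs
whose pathways all hit stops skipped with a warning), site counts averaged
over the two sequences, and Jukes–Cantor correction. The genetic code is
configurable by NCBI table id and defaults to the standard code, since
published organelle analyses of this kind do not state the table their
Ka/Ks runs used. NG86 variants differ exactly in these stop-handling
details, which is why they are spelled out here. The ratio is undefined
(NA) when Ks is 0 or a proportion reaches 3/4.

## What the simulator emulates — and what it does not

The generator builds an annotated ancestor from a blueprint of regions and
evolves it along a known tree. Its defaults state the world the analyses
are tested in:

* `gc_target = 0.333` — organelle genomes in this range are AT-rich
  (~32–34% GC).
* `kappa = 2.8` — with near-equal base usage the observed
  transition/transversion count ratio is about `kappa/2`, and organelle SNP
  surveys in this genus report ratios of ~1.4–1.5.
* `omega = 0.1` per genic region — organelle protein-coding genes are
  strongly purifying-selected; a proposed nonsynonymous change is accepted
  with probability `min(1, omega)`, synonymous changes always, and changes
  creating stop codons never.
* `indel_rate = 5e-4` per site per unit branch length, with genic indels
  forced to length 3 — published coding-region indels in such genomes are
  frame-preserving triplets essentially without exception.
* Substitutions are applied sequentially with replacement (multiple hits
  allowed); the truth records realized, not proposed, events, and replaying
  the recorded events from the ancestor must reproduce each leaf exactly —
  this replay is a standing test.
* The ancestor generator breaks chance perfect repeats within 2 nt of the
  SSR thresholds, so that planted SSRs are the only loci at or above
  threshold and recovery can be scored as precision = recall = 1.

The simulator does **not** model rearrangements, inverted-repeat structural
evolution, recombination, gene transfer to the nucleus, or codon-frequency
mutation bias. A green test on simulated data therefore establishes that
the statistics and search procedures behave correctly under the stated
generative model — not that any particular biological genome satisfies that
model. Calibration tests that compare NG86 estimates against the
simulator's `omega` run with `kappa = 1`, because NG86 site counting
assumes no transition bias; with a realistic `kappa` the method is known to
be conservatively biased.

## Numerical choices and degenerate inputs

* Coordinates are GFF3-style 1-based inclusive at every interface and
  0-based half-open internally; the conversion lives in a single audited
  helper. Features may wrap the origin of a circular genome (`end <
  start`).
* Orthology is exact feature-name matching. Duplicated names within a
  genome (e.g. the two inverted-repeat copies of a plastid gene) are a hard
  error: the caller must disambiguate (`psbV` vs `psbV_1`), because
  guessing which copy is orthologous would silently corrupt every
  downstream index.
* Overlapping or abutting features yield no intergenic region for that
  pair; `N` is treated as missing everywhere (excluded from p-distances,
  `S`, and Fitch costs); columns of an alignment that are all gaps are
  invalid by construction.
* Negative NJ branch lengths are clamped to zero with the deficit shifted
  to the sister edge. Multiallelic columns (three or more bases) are
  tallied separately in SNP summaries rather than forced into the
  transition/transversion dichotomy, and the partition
  `transitions + transversions + indel columns + multiallelic = variant
  columns` is exact.
* Regions with fewer than four members get sensitivity only and are never
  consistent; a two-taxon NJ "tree" exists only behind a permissive flag.

## Known limitations

The center-star aligner can misplace gaps in repetitive or highly diverged
regions; the anchored genome aligner requires collinearity and refuses
reversed or rearranged inputs rather than producing a misleading alignment.
Exhaustive MP is exponential and hard-capped at 9 leaves. SSR comparison
keys on the flanking-locus name, so unannotated genomes can only be
compared positionally. The pipeline's percentage ratios of evolutionary
rates are reported to whole percent, which is the precision such summaries
usually carry.
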