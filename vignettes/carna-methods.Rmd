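---
title: "Methods: RNA-chromatin interactome landscape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RNA-chromatin interactome landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carna)
```

# The analysis model

`carna` analyses RNA–DNA contact pairs of the kind produced by
iMARGI/GRID-seq-style proximity ligation: each valid read pair has an RNA
end (the transcript fragment) and a DNA end (the chromatin locus it was
crosslinked to). The package starts where upstream read processing ends —
alignment, valid-pair calling and deduplication are out of scope and
assumed done — and models three things: where each contact came from,
whether it is local, and what chromatin context it lands in.

## Coordinates

All internal coordinates are 0-based half-open; conversion to and from the
1-based conventions of the pairs dialect and GTF happens only in the
parsers and writers. A single internal convention removes the most common
source of off-by-one drift in interval code, and the involution
(0-based → 1-based → 0-based is the identity) is tested directly.

## Source-gene assignment

The pairs format does not say which gene a contact's RNA end came from;
some assignment rule is required and none is canonical. The rule used here
is declared, configurable and logged:

1. Candidate genes are the **same-strand** overlaps of the RNA end. The
   RNA end derives from a transcript, so an antisense overlap is not
   evidence of origin; `allow_antisense = TRUE` relaxes this.
2. Ties are broken by **class priority** (default
   snoRNA ≻ snRNA ≻ miRNA ≻ rRNA ≻ other ncRNA ≻ lncRNA ≻ protein-coding),
   then by largest overlap, then by lexicographically smallest gene id.
3. No candidate means `unannotated`; such contacts stay in the dataset
   (their locality is still defined) but are excluded from per-class
   statistics, because "unannotated" is not an RNA class.

The class priority is the load-bearing choice. Many snoRNAs live inside
the introns or UTRs of host genes (the SNHG-family arrangement): without
small-ncRNA-first priority, every read from a nested snoRNA would be
credited to its host and the small-ncRNA landscape would be empty. The
package treats the priority as configuration, and the test suite includes
the negative control: inverting the priority collapses snoRNA attribution
onto the hosts.

## Locality

A contact is **cis** when both ends map to the same chromosome — at any
distance — and **trans** otherwise. No proximal-distance cutoff is
applied; the definition is purely chromosomal, so `n_cis + n_trans =
n_total` exactly, and this conservation is asserted on every fixture.

## The class landscape

Per class the package reports cis and trans counts, the class's share of
all annotated cis contacts, its share of all annotated trans contacts,
and the trans fraction within the class. The global cis fraction is
computed over all contacts including unannotated ones. Empty denominators
yield explicit `NA`, never a silent 0.

## Trans-acting RNA calling

A gene is called trans-acting when it shows frequent chromatin
association and a substantial trans proportion:

- `n_total >= min_contacts` (default 10), and
- `n_trans / n_total >= min_trans_fraction` (default 0.20),

both inclusive at the boundary. The denominator is all of the gene's
annotated contacts, cis plus trans. Called genes are ranked by trans
contact count (ties: trans fraction, then gene id), which is the quantity
"top trans-acting gene" lists highlight. The caller is a fixed dual
threshold, not a statistical test against a background model — that is
the operational definition this style of analysis uses, and the
exhaustive grid test (`n_total` up to 30, every `n_trans`) pins the
boundary behaviour against brute-force enumeration.

## Per-RNA interaction maps

For one focal gene, DNA ends of its contacts are binned genome-wide
(default 1 Mb bins) and exported as an arc table — source gene span,
target bin, cis/trans label, count — consumable by circos-style plotters.
Bin frequencies sum exactly to the gene's contact total; the package
exports data, not images.

## qPCR enrichment

Library-verification qPCR measures the enrichment of an RNA–DNA
interaction as the ratio of amplification of the chimeric product to
amplification of the RNA alone: `efficiency^(ct_rna - ct_pair)`. The
efficiency defaults to 2.0 (perfect doubling per cycle) because assays
rarely report a calibrated value; it is a parameter, not a constant.

## Chromatin overlay

Signal enters as bedGraph (text, non-overlapping records), is binned into
fixed-width bins (each bin the coverage-weighted mean of overlapping
records, uncovered bases contributing zero), and is CPM-normalized by
explicit library size. Region scores are length-weighted means of bin
values over the region — the computeMatrix-style enrichment score — and
are checked against a per-base accumulation oracle to 1e-9.

Clustering of contact regions into activity states C1..Ck uses k-means on
the column-z-scored score matrix. The clustering algorithm, distance and
normalization behind published heatmap groupings are typically
unreported; k-means with z-scored columns is declared here as the
package's own choice because it is simple, deterministic given a seed,
and matches heatmap-style grouping practice. Defaults: `k = 4` (the C1–C4
convention), 50 random restarts (few, widely separated, tight clusters
make single-start k-means prone to local optima; restarts are cheap
insurance), and cluster labels ordered by descending mean raw H3K27ac so
that C1 is the transcriptionally active state (high H3K27ac/H3K36me3).
All of these are arguments, not constants.

Condition comparisons report per-region
`log2((score_b + pc) / (score_a + pc))` with a pseudocount (default 1
CPM) guarding unmarked regions; identical tracks give identically zero
ratios, which is asserted as a property.

# The synthetic-data generator

The generator exists so that every stage has truth-known inputs; its
defaults *are* the study conditions the package is validated under, and
they are not tuned per test.

- **Genome**: `n >= 2` chromosomes (trans needs somewhere to go);
  desk-scale defaults of a few megabases per chromosome keep the full
  suite fast while leaving thousands of bins per chromosome.
- **Annotation**: per-class gene counts with field-realistic length
  ranges (snoRNAs 70–200 bp, snRNAs 100–200 bp, lncRNAs 5–20 kb,
  protein-coding 5–50 kb); non-host genes are non-overlapping; a
  configurable fraction of snoRNAs is nested strictly inside same-strand
  lncRNA hosts.
- **Contacts**: gene drawn by expression weight; RNA end uniform within
  the gene on its strand; locality Bernoulli with per-class trans rates
  defaulting to protein-coding 0.02, lncRNA 0.03, snoRNA 0.8, snRNA 0.8 —
  the qualitative structure of the landscape this package is built to
  detect: a ~97%/3% global cis/trans split at realistic class mixes, with
  small ncRNAs predominantly trans. Cis DNA ends fall at an
  exponentially distributed distance from the gene midpoint (default
  scale 50 kb) — the simplest single-parameter monotone decay consistent
  with contacts concentrating at or near the transcription site; the
  kernel is pluggable in the sense that the config exposes the scale and
  the draw is isolated in one place. Trans DNA ends are uniform on a
  uniformly chosen other chromosome; trans *target* hotspots are
  deliberately not modelled, because the downstream statistics test
  locality, not target identity. Hotspot *source* genes (elevated trans
  rate, elevated coverage) are supported for caller validation.
- **Tracks**: each region gets a planted cluster label; its per-mark
  signal is the cluster signature plus truncated Gaussian noise, rendered
  through the same binning code the readers use. The default signatures
  encode four states from active (high H3K4me3/H3K27ac/H3K9ac/H3K36me3)
  to polycomb-repressed (high H3K27me3), separated by many noise SDs so
  that exact recovery (ARI = 1) is the correct expectation.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: ligation artifacts and PCR
duplicates, mappability and coverage biases, nascent-transcription
gradients along gene bodies, exon/intron structure, chromatin-domain
(A/B-compartment) structure in cis decay, and trans contacts concentrated
at specific target loci. Recovery results on synthetic data validate the
*computation*, not the biology of any particular library.

# Numerical and design notes

- **Problem sizes.** The validation studies use a 1,000,000-pair library
  for the global cis/trans split, 200,000 pairs for per-class rates,
  20 × 10,000-pair replicates for the caller, and 200 regions × 6 marks
  for clustering — sizes chosen so that binomial standard errors are far
  smaller than the effects being recovered while the whole suite runs in
  well under a minute per study.
- **Tolerances.** Monte-Carlo recoveries are asserted within 3 binomial
  standard deviations of truth; deterministic numerics (binning, region
  scores) within 1e-9 of brute-force oracles; count identities exactly.
- **Degenerate inputs.** Empty pairs files yield empty streams, not
  errors; empty landscapes report `NA` shares; an all-constant score
  matrix refuses to cluster (with advice to use k = 1) rather than
  returning arbitrary labels; unknown chromosomes in pairs and GTF are
  skipped and counted (real files contain scaffolds), while unknown
  chromosomes in BED region sets are errors (region sets are curated
  inputs).
- **Determinism.** Every stochastic operation takes a seed; identical
  seeds give byte-identical outputs, and the pipeline manifest records
  seed, config and input checksums so a run is fully specified by
  config + inputs.
- **Open choices decided here.** The RNA-end→gene rule (same-strand,
  priority, largest-overlap, id tie-break) is this package's declared
  rule, not a reconstruction of any published pipeline's unstated one.
  Whether per-class "trans-acting" percentages should use expressed or
  all annotated genes as denominator is ambiguous in the field; the
  package reports raw counts and lets the caller choose a denominator.
  Upstream deduplication is assumed; the package does not re-deduplicate.

# Known limitations

Single-position RNA/DNA ends (the pairs dialect's convention) rather than
aligned fragment intervals; gene-level (not transcript-level) assignment;
no statistical background model for trans enrichment; bigwig signal is
not read (bedGraph is the interchange format — text, testable, no binary
dependency); heatmap/circos rendering is left to dedicated plotters.
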