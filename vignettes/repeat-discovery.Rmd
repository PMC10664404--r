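---
title: "Repeat discovery and comparative statistics for giant-virus genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat discovery and comparative statistics for giant-virus genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvrepeats)
```

## The problem

Pithovirus genomes (circular dsDNA, ~600 kb, AT-rich) are shaped by two
families of short palindromic MITE-like elements, conventionally called M1
and M2.  They occur in dense clusters — repeat-rich regions — organised as
`(M1-M2){n}-M1`, carry terminal inverted repeats (TIRs) and a `TA`
target-site duplication (TSD), and cover around a fifth of the genome.
`gvrepeats` detects these regions and elements from nothing but the genome
sequence, clusters the elements into families, checks the structural
grammar of each region, and provides the comparative statistics that such
repeat maps feed into: pan/core-genome rarefaction and Heaps'-law openness,
gene-duplication fractions, codon usage (RSCU), proteome-wide amino-acid
identity (AAI), a counting dN/dS estimator, and enrichment/trend tests for
genes inside repeat-rich regions.

## The detection model

Detection works on the genome's self-alignment coverage:

1. **Self-alignment.**  The genome is aligned against itself.  The internal
   backend seeds on exact words (default 12 nt), extends each seed without
   gaps under an X-drop criterion, and assigns Karlin–Altschul E-values
   comparable to BLASTN's ungapped statistics; hits with E > 1e-10 are
   discarded and the trivial full-length self-hit is never formed.
   Precomputed hits in the standard 12-column tabular format can be
   imported instead, so an external BLASTN run is a drop-in backend.
2. **Coverage vector.**  Each hit increments every position of its query
   and subject intervals, giving the flattened-dotplot vector `y`.
3. **Regions.**  `y` is smoothed by a circular sliding mean (window
   `region_window`, default 500 nt; 4000 nt for the broader regions used in
   gene statistics), and regions are maximal runs where the smooth vector
   exceeds the threshold τ.  The threshold is `mean(ys)/sensitivity` with
   sensitivity 2.5; see *Numerical choices* for the alternative reading of
   the τ expression and why this one is the default.
4. **Units.**  Within each region, element boundaries are local maxima of
   the absolute smoothed derivative of `y` (sliding mean of window 20
   applied before the first difference and after taking the absolute
   value) that exceed a cutoff of 10; consecutive boundaries delimit
   units.

Two implementation points deserve emphasis because they follow from the
palindromic biology rather than from generic alignment practice:

* **Co-diagonal hit chaining.**  A palindromic element aligned to another
  copy in the reverse orientation scores well over both TIRs but poorly
  over the internal sequence.  Trimming an ungapped extension at its score
  maximum therefore keeps only one TIR segment for an appreciable fraction
  of copy pairs, which would put large artificial coverage steps at the
  TIR/internal junctions and fragment every element into TIR–internal–TIR
  units.  The aligner therefore chains co-diagonal hits separated by at
  most 50 nt into a single hit — the same nonredundant-HSP treatment that
  gapped aligners achieve with their larger X-drop — restoring uniform
  within-element coverage.
* **Scale of the derivative cutoff.**  After sliding-mean smoothing, the
  first-difference derivative of a coverage step of height *h* peaks at
  about *h*/window.  A cutoff of 10 with window 20 therefore delimits
  steps of roughly 200 copies of coverage and is calibrated for
  repeat-dense genomes with hundreds of element copies; genomes (or
  simulations) with far fewer copies need a proportionally smaller
  cutoff.  The cutoff is exposed in `detection_params()`.

## Clustering and annotation

Units are globally aligned to each other with needle-style scoring (match
+5, mismatch −4, gap open 10, gap extend 0.5; identity = matches over all
alignment columns including end gaps), ordered by mean distance to their 10
nearest neighbours, and greedily clustered at 70% identity against a
growing reference list; clusters are merged when more than half of each
cluster's members match the other's reference, and the two most populous
clusters are labelled M1 and M2 (smaller clusters matching their references
become M1-/M2-like).  The grammar validator checks the four structural
rules (M2 never without M1; M1 may stand alone; consecutive M1 separated by
about 140 nt; an M1 between any two M2).  TSDs are the longest exact
duplication flanking both ends of an element or region on the circular
sequence; TIRs are measured in the palindrome frame with a terminal-window
rule (last 8 positions ≥ 75% matching, last position matching) so that
diluted mismatches cannot silently extend a TIR into the internal
sequence.

The 140-nt spacer is measured **end-to-start** between consecutive M1
units.  The elements themselves are 145 nt (2 × 54 + 37), so a
start-to-start reading of "separated by about 140 bases" is geometrically
impossible; the separating sequence is what carries the M2 element when
one is present.

## The synthetic-data generator

`simulate_genome()` emulates the observables the analysis assumes: a
circular ~600 kb i.i.d. background at GC 0.36, 100 planted regions of
`(M1-M2){n}-M1` structure with n uniform on 1..8, family consensus built as
TIR + internal + reverse-complemented TIR (54/37 for M1, 47/37 for M2),
per-copy substitution divergence 2%, inter-M1 gaps of 140 ± 1 nt with the
M2 centred inside, `TA` TSDs flanking each region, and interleaved ORFs.
An optional `region_drift` makes copies from the same region more alike
than copies from different regions (the concerted-evolution signature).
The planted truth (regions, units, families, genes) is emitted alongside.

What it does **not** emulate: indels within elements, nested or truncated
elements, compositional heterogeneity of the background, other repeat
classes, and real gene structure.  Passing tests on these simulations
therefore demonstrate that the pipeline recovers the stated structure under
substitution noise at realistic copy numbers, not that it handles every
artefact of real assemblies.

`simulate_hog_matrix()` builds orthologous-group count matrices with a
core, a shared accessory pool (per-HOG presence probabilities drawn from a
Beta distribution, making the permutation-averaged new-HOG curve decay as a
power law with exponent a+1 — `heaps_expected_new()` gives the closed
form), genome-specific novel HOGs, and a target duplication fraction.
`simulate_cds_pair()` evolves codon pairs at a known dN/dS by accepting
synonymous proposals always and nonsynonymous ones with probability ω.
`simulate_ipd_track()` plants base-modification calls at a chosen per-kb
rate over a gamma baseline.

## Comparative statistics

* **Rarefaction** uses presence/absence, iterating genomes in all orders
  (uniformly subsampled above 5000 orders); core is non-increasing and pan
  non-decreasing along every ordering by construction.
* **Heaps' law** fits `new(n) = κ·n^(−α)` to permutation-averaged new-HOG
  counts by least squares on the log–log scale, excluding n = 1; α < 1 is
  an open pan-genome.  A matrix that never yields a new HOG past the first
  genome reports α = ∞ (closed).
* **Duplication fraction** counts copies in excess of one per HOG by
  default; counting all members of multi-copy HOGs is available as
  `mode = "all"` (it shifts values upward).
* **RSCU** is computed on all codons pooled, excluding stops and the
  single-codon families (Met, Trp), leaving 59 codons whose family means
  are 1 by construction.
* **AAI** takes reciprocal best-hit pairs from local BLOSUM62 alignments,
  keeps pairs with identity ≥ 15% covering ≥ 0.4 of the shorter protein,
  and averages identities; "-L 0.4" is read as an aligned-length fraction.
* **dN/dS** is the Nei–Gojobori counting estimator with Jukes–Cantor
  correction (all shortest codon paths, stop-passing paths excluded),
  replacing the ML engine the filters were designed around; estimates are
  kept when 0.1 < dS < 1.5 and dN/dS < 10.  Counting estimators are
  adequate for the rank-based inside/outside comparisons made here.
* **Gene-in-region** membership uses the midpoint rule by default to avoid
  double counting at boundaries; ≥ 1 bp overlap is available.
* Enrichment uses Pearson's chi-squared without continuity correction, the
  ancestry trend the Cochran–Armitage test with integer scores ordered
  root→leaf, placement uniformity a one-sample KS test of region midpoints,
  and all per-genome tests are reported raw, without multiplicity
  correction.

## Numerical choices

* **τ precedence.**  The threshold expression "mean(ys) * sensitivity − 1"
  admits two readings.  The default reads the trailing "−1" as an inverse —
  τ = mean(ys)/sensitivity — because a *sensitivity* coefficient must lower
  the threshold as it grows; the affine reading
  `mean(ys)·sensitivity − 1` is available as `tau_mode = "affine"`.  Note
  the geometric consequence: with the divide reading the crossing of the
  smoothed coverage with τ sits low on the flanks, so reported region
  boundaries extend roughly 200 nt beyond the dense element span on each
  side (and the affine reading conversely trims them), independently of
  repeat copy number.  Masked fractions are correspondingly larger than
  the strict element content.
* **Derivative.**  First difference with circular wrap; strict 3-point
  local maxima; plateaus take the leftmost position for determinism.
* **Circularity.**  Coverage, smoothing and derivatives are computed on
  the circular sequence; a region running through the linearization origin
  is reported split at the origin and flagged `wrapped`.
* **Ambiguity.**  `N` never matches anything in any aligner; the simulator
  never emits it.
* **Ties.**  Unit ordering ties break by genomic coordinate; equal-score
  alignment paths resolve in a fixed state order; cluster merging keeps the
  larger cluster's reference.
* **End gaps** are penalized in the global aligner and counted in the
  identity denominator.

## Problem sizes used in the checks

The end-to-end checks run the full study conditions: one 600 kb genome
with 100 planted regions (about 950 elements), detection at the printed
parameters, and clustering of all recovered units (about 450k pairwise
global alignments) — a few minutes on one CPU.  Openness classification
uses 100 simulated matrices per regime with 200 permutations each;
rank-based and trend tests are verified against permutation oracles at a
few hundred genes; dN/dS recovery uses 50 replicate 300-codon pairs.

## Known limitations

* The internal self-aligner is ungapped (with co-diagonal chaining);
  repeat copies diverged by indels are recovered as chained or split hits
  rather than single gapped alignments.  The tabular import path exists
  for users who prefer an external gapped aligner.
* Real M1/M2 reference sequences are not distributed with the package, so
  family labels on real genomes follow cluster-size rank unless reference
  sequences are supplied.
* Region boundaries are threshold crossings of a smoothed vector and
  inherit its resolution (about half the smoothing window); they are not
  base-precise element bounds.  Use the unit table for element-level
  coordinates.
* Folding energies, GO-term enrichment and HGT donor inference are out of
  scope; HGT labels, trees and orthology tables are inputs.

## A short walk-through

```{r example, eval = FALSE}
sim <- simulate_genome(sim_config(genome_length = 6e5, n_regions = 100,
                                  seed = 7))
scan <- detect_repeats(sim$genome)
summary(scan)
cl <- label_m1_m2(merge_clusters(greedy_cluster(scan$units)))
print(cl)
grammar <- lapply(split(cl$units, cl$units$region_id), validate_grammar)
mean(vapply(grammar, `[[`, TRUE, "well_formed"))
```
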