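---
title: "Typing heme a synthases: models, parameters and design choices"
author: "HAStyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing heme a synthases: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HAStyper)
```

## The problem

Heme *a* synthase (HAS, the Cox15/CtaA family) is an integral membrane
enzyme that oxidizes the C8 methyl group of heme *o* on the path to heme
*a*, the cofactor of *aa3*-type terminal oxidases. The family divides into
types distinguished by three signals:

* the number of transmembrane (TM) helices — four for the short archaeal
  type 1A, eight for everything else;
* conserved cysteine pairs in the periplasmic loops: type 1B carries a pair
  in both ECL1 and ECL3 (loops L1 and L5 in an 8-TM architecture), types
  1A, 1A\* and 1C in ECL1 only, and types 0, 1D and 2 none;
* sequence relationships, summarized here as mean global identity to
  per-type reference panels, with phylogenetic placement as the
  verification instrument.

Two short conserved blocks carry most of the diagnostic residue signal: the
helix-II block E57–X1–X2–H1–R around the catalytic glutamate and the first
conserved histidine, and its less conserved helix-VI "mirror" block
X1–X2–X3–H3–X4. Four histidines (H1–H4, helices II, IV, VI, VIII) frame
the heme-binding core; H1 tolerates asparagine in part of type 1C, and in
type 1A\* the H3 position is frequently phenylalanine.

`HAStyper` implements the full desk-scale analysis around this
classification: homolog filtering and clustering, a hydropathy-based
topology stand-in, the rule-cascade classifier, motif conservation tables,
±5-gene synteny statistics, per-lineage distribution matrices, and
phylogeny-side verification (minimal-ancestor-deviation rooting, monophyly,
minimum-transition counts). Because the family's reference datasets are
database-scale, every stage is driven and tested through a seeded
synthetic-data generator that emulates the statistical structure the
analysis assumes.

## The synthetic-data generator

`genSequence()` realizes a `TypeProfile`: `nTM` hydrophobic helices
separated by polar loops, a cytoplasmic N-terminus, cysteine pairs planted
in the designated periplasmic loops (intra-pair spacing 4–8 interleaving
residues, inside the detector's [2, 12] window), and motif residues drawn
from per-type frequency tables whose named entries transcribe the observed
per-type conservation percentages (e.g. Trp at X1 in 85% of type 1A,
Asn at H1 in 34% of type 1C, Phe at H3 in 55% of type 1A\*); residual
probability mass is uniform over the remaining residues.

Three design layers matter:

**Detectability by construction.** The topology stand-in `predictTM()` is a
classic Kyte–Doolittle sliding-window detector (window 19, threshold 1.6,
minimum segment 15, merge gap 3, per-side extension 2). The generator's
residue pools are chosen so that recovery of the planted architecture is
guaranteed, not merely likely: TM helices draw from {I, V} (plus 10%
leucine outside the motif helices), loops and termini from {D, E, N, Q}
with lysine added only on the cytoplasmic side. With these pools a window
mean stays above threshold whenever it contains at most six loop residues
and falls below it from seven on, which (i) keeps every helix's center run
long enough, (ii) guarantees a below-threshold gap over every loop of
length ≥ 9, and (iii) makes the positive-inside N-terminal call
deterministic (periplasmic loops contain no K/R at all). Helix lengths are
21–24 for plain helices; the motif-bearing helices II and VI are fixed at
32 and the H2/H4 anchor helices at 28, with the planted polar blocks
centered so that no edge window mixes loop residues with motif residues.
A shorter plain-helix floor would make an 18-residue helix invisible to
the detector's default window/minimum combination, which is why the
generator does not go below 21.

**A scaffold per type.** Each profile carries a deterministic type-specific
template sequence; records are the scaffold with per-residue substitutions
(15% in helices, 30% in loops) and loop-length resampling. This gives the
corpus the identity structure the classifier needs — within-type identity
far above between-type identity, between-type still above the 25% homology
floor — mirroring the real family, where inter-type global identities are
low but above 20%. Without the scaffold, panel-based resolution of
1A\*/1C and 0/1D/2 would rest on ~10 motif residues and be statistically
fragile.

**Neighborhood and fusion structure.** `genGenome()` plants a HAS gene on a
contig and places neighbor families inside the ±5-gene window by per-type
probabilities; the HOS and cytochrome-oxidase probabilities are set to the
published per-type co-occurrence fractions (e.g. 2,140/2,339 for HOS next
to type 1B), the remaining families (SCO1, DUF1507, pyruvate carboxylase,
FtsW, ribosomal S9/L13 analogues) to qualitative levels. Type-1A records
become HAS–HOS fusions with probability 154/273. The HOS and DUF420
stand-ins use residue pools disjoint from the HAS pools: this makes local
alignments stop at the HAS/HOS domain boundary (so fusion footprints
separate cleanly) and keeps the decoy family sub-homologous (mean/median
global identity to every type panel far below 25%, reproducing the
argument for excluding DUF420 from the family's phylogenies).

What the generator does **not** emulate: realistic substitution processes
along a tree (records within a type are exchangeable, not phylogenetically
correlated), nucleotide-level gene structure, signal peptides,
length/composition diversity of real proteomes, and annotation noise.
Passing tests therefore demonstrate that the pipeline's logic is correct
under its stated assumptions, not that the heuristics (e.g. the hydropathy
stand-in) match HMM-grade predictors on real membrane proteomes.

## Alignment and gating

`nwAlign()`/`swAlign()` are exact affine-gap Needleman–Wunsch /
Smith–Waterman implementations (Rcpp) with the EMBOSS gap convention — a
gap of length L costs `open + (L−1)·ext`, defaults BLOSUM62, 10/0.5 — and
end gaps penalized. Tie-breaking is fixed (diagonal, then gap-in-second,
then gap-in-first), so alignments are reproducible. Any square matrix over
any alphabet is accepted; 3Di structural strings align with their own
matrix through the same code path. Global identity uses the needle
convention (identities over all alignment columns, gaps included); the
shorter-sequence denominator is available as an option since the EMBOSS
configuration behind published identities is not always stated.
`homologyGate()` requires mean **and** median above 25% — the canonical
homology floor below which alignment-based phylogenetics is unreliable.

Hit filtering is strict on identity (> 25%) and inclusive on E-value
(≤ 1e-10), exactly as printed gates are usually meant: a 25.0%-identity
hit is removed, a 1e-10 hit kept.

## Clustering

`greedyReduce()` is CD-HIT-style greedy incremental clustering at 90%
identity but with exact global alignments (desk-scale corpora make k-mer
screens unnecessary); sequences are visited longest-first with id-order
tie-breaks, so the partition is deterministic. `mclCluster()` implements
canonical Markov clustering (expansion, inflation 2.0, pruning 1e-5,
column renormalization; clusters from the converged support's connected
components). The inflation default is MCL's canonical value. For the
similarity input no transform is prescribed upstream, so the package
accepts any non-negative symmetric matrix and the pipeline documents mean
bidirectional bitscore as its default choice, with −log10 E-value or
percent identity as drop-in alternatives. `mergeClusters()` joins cluster
pairs whose inter-cluster mean **and** median identity exceed 25% and takes
connected components, so merging is transitive by construction.

## Typing and motifs

The classifier cascade is described in `?assignType`. Numerical choices:

* TM-count bands [3, 5] and [7, 9] absorb predictor wobble around the true
  4/8 helix counts.
* The cysteine spacing window [2, 12] brackets the two classical exemplar
  pairs (spacings 6 and 5); the operational definition of a "conserved
  pair" is nowhere printed, so the window is deliberately generous and
  configurable.
* 1A\* vs 1C is resolved by reference identity first; H3 = Phe breaks
  near-ties toward 1A\*; taxonomy (Halobacteria-restriction of 1A\*) is
  deliberately *not* used so the classifier works without a taxonomy
  table.
* 0/1D/2 need a ≥ 2-identity-point margin between best and runner-up
  panel, else the record is flagged ambiguous and left to phylogenetic
  verification (`verifyTypes()`), mirroring how such cases are resolved by
  tree placement.
* Motif tables round half-up to integers; co-occurrence fractions to one
  decimal — the precisions used in print.

`locateMotifs()` anchors on the helix-II segment center (a quantity
invariant under the predictor's symmetric boundary wobble), searches
`E..[HN]R` within ±8 residues and takes the match closest to the anchor;
the helix-VI mirror block has no invariant residues and is read
positionally at the TM VI center. An annotated reference alignment is the
alternative strategy; absence is reported as such, never imputed.

`trimMSA()` drops columns below 5% occupancy and then, if fewer than 60%
of the original columns survive, restores the fullest dropped columns
until the floor is met. The floor interpretation (minimum retained
proportion, as in trimAl's `-cons`) was chosen over a per-column
conservation score because the latter would need a scoring definition the
method's description does not give.

## Synteny and distribution

Windows are positional (±5 genes on the contig by start coordinate,
truncated at contig ends); upstream/downstream are not reoriented by focal
strand, matching fraction-style reporting that does not distinguish
orientation (a strand-aware mode is one flag away). Co-occurrence uses
presence semantics (≥ 1 labelled neighbor per window) with the per-type
record count as denominator — the convention that reproduces printed
fractions such as 2,140/2,339 → 91.5%. Fusion records count as
self-containing their partner label. Distribution matrices report, per
lineage (phylum, or class within Euryarchaeota), the percentage of
assemblies with ≥ 1 record of each type; configured hit-free lineage sets
can be collapsed into one display row.

## Phylogeny-side verification

`madRoot()` implements minimal-ancestor-deviation rooting from its
definition: for a candidate root, each leaf pair's ancestor is the point of
the pair path nearest the root, the pair deviation is
`|2·d(anc,i)/d(i,j) − 1|`, the branch score is the RMS over all pairs, and
the optimal position on each branch has a closed form because the
objective is quadratic in the position. Zero-length branches are perturbed
by 1e-8. The test suite checks the minimizer against a dense per-branch
grid scan written in an independent formulation (root-to-leaf distance
differences). `minTransitions()` uses unit-cost Sankoff dynamic
programming (Fitch-equivalent on binary trees, valid on polytomies,
root-invariant), with an exhaustive enumeration oracle on small trees;
binarizing on a focal label gives the minimum number of independent
gains/losses of, e.g., a cysteine pair. `verifyTypes()` operationalizes
"verified by placement in the phylogeny" as a patristic k-nearest-neighbor
majority vote (k = 5), flagging conflicts and resolving ambiguous
assignments only on near-unanimous neighborhoods.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed and restores the
caller's RNG state; identical configuration and seeds give byte-identical
outputs. The shipped experiments use corpora of 2,000 records per type for
motif-frequency recovery (binomial noise ≈ ±2 points at the published
frequencies), 100 records per type for whole-corpus classifier recovery,
and 50–500 cases for the oracle-equivalence suites; these sizes make each
suite complete in well under the generator's statistical convergence
scales and are stated here as the package's chosen experiment sizes.

## Known limitations

* The hydropathy TM stand-in is calibrated for the generator's pools and
  easy real cases; it is not a TMHMM replacement, and real-world topology
  should be supplied via the topology TSV or TMHMM parser.
* Reference panels default to generator exemplars; classifying real
  sequences requires swapping in curated panels (same list shape).
* The headline dataset-scale quantities (8,093 sequences from 35,307
  assemblies, 12 MCL clusters) depend on a database-scale search that is
  out of scope; the package reproduces the per-type arithmetic, the
  stochastic parameter-recovery experiments, and all algorithmic
  invariants at desk scale.
* Mirror-motif reading on *predicted* (rather than truth) topologies can
  shift by one residue when boundary wobble is asymmetric; the
  reference-alignment strategy avoids this.
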