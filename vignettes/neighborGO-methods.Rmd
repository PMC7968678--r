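---
title: "Genome-neighborhood features for multi-label GO prediction: models and methods"
author: "neighborGO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-neighborhood features for multi-label GO prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neighborGO)
```

## The idea

In prokaryotes, genes that stay chromosomal neighbors across evolutionarily
distant genomes tend to work in the same pathway or complex: operons and
conserved gene clusters are a functional signal that survives even when
sequence similarity to characterized proteins is weak. neighborGO exploits
this signal for photosynthesis: instead of classifying a protein by its
sequence, it classifies it by *who its conserved neighbors are*, and assigns
photosynthesis-specific GO terms with a multi-label classifier. The default
label vocabulary is a curated set of 24 photosynthesis-specific GO terms
(children of photosynthesis observed in photosynthetic prokaryotes, plus
phycobilisome, which is connected to photosynthesis through the
photosynthetic membrane); any other vocabulary can be substituted.

## The pipeline, stage by stage

### Neighborhood calling

Two adjacent genes on the same strand belong to one neighborhood cluster
when their intergenic gap is at most 250 bp (inclusive); overlapping genes
have non-positive gaps and always join. Clusters are maximal runs of
consecutive genes, so an interleaved opposite-strand gene terminates a run.
A second rule captures divergently transcribed pairs, which share an
upstream regulatory region: an all-minus-strand cluster followed by an
all-plus-strand cluster merges when the gap between them lies in 200–1000 bp
(inclusive). The merge is applied once, left to right; a merged,
mixed-strand cluster never merges again. Gaps are measured between annotated
gene bounds in 0-based half-open coordinates, which makes gap arithmetic
exact (`gap = start(next) − end(prev)`).

Contigs are linear by default. A per-contig circular flag exists in the data
model, but wraparound neighborhoods across the origin are not computed:
origin-spanning operons are rare in annotation practice (most annotation
pipelines rotate contigs away from gene boundaries), and the added rule
complexity is not warranted without a ground-truth case to pin it.

### Homology tiers

Proteins are grouped into families as connected components of the pairwise
similarity graph at an E-value cutoff, with three tiers (1e-10, 1e-50,
1e-100) spanning the similarity range observed among photosynthetic protein
families. An asymmetric hit pair contributes its better direction as the
edge weight; duplicate hits resolve to minimum E-value, then maximum
bitscore. Components give single-linkage behavior — the most permissive
choice, which the stricter tiers counterbalance; cluster ids are the
lexicographically smallest member, so ids are stable across runs and input
orders. Stricter tiers provably refine looser ones, which the test suite
checks on random hit graphs. External query proteins enter the database by
their best hit at E ≤ 1e-25, keeping at most one match.

### Conservation (Phylo) scores

The conservation score of a (focal family, neighbor family) adjacency is
defined as the phylogenetic diversity — the total branch length of the
minimal spanning subtree — of the set S of genomes in which some member of
the focal family shares a neighborhood cluster with some member of the
neighbor family, measured on a genome tree. The tree is built by neighbor
joining from Jaccard distances on protein-family content
(`1 − |A∩B|/|A∪B|`), with negative NJ branch estimates clamped to zero.
An adjacency seen in at most one genome scores exactly zero — zero *means*
nonconserved — and an adjacency conserved everywhere scores the total tree
length. This definition has the properties that matter: it is monotone in S
(adding a supporting genome never lowers the score), bounded by the total
tree length, and it weights distant genomes more than near-identical ones,
so a clade of trivially similar genomes cannot inflate conservation the way
a raw co-occurrence count would.

Distances, trees and scores are computed per homology tier; the modeling
tier defaults to 1e-10, the most inclusive.

### Discretization

Raw scores are mapped to ordinal bins {0,1,2,3}: zero stays 0, and the
strictly positive training scores are split at their 1/3 and 2/3 empirical
quantiles (linear interpolation of the empirical CDF, `type = 4`, under
which positive scores 1..9 give cutoffs exactly 3 and 6). The upper bin is
open, so a prediction-time score beyond the training range maps to 3. With
fewer than three distinct positive scores both cutoffs fall back to the
median, with a warning — discretization is then coarse but never undefined.

### Features, labels, instances

Instances are *proteins*, not families: homologous proteins with different
annotations stay distinct instances with identical feature rows, which keeps
the label matrix faithful to the annotation table. A feature column is a
neighbor family ever observed adjacent to an instance's focal family; the
value is the discretized conservation score, absent neighbors are 0. The
column order is serialized as a feature registry; at prediction time,
columns unseen in training are dropped (and counted) rather than hashed, so
model dimensionality is fixed. Proteins with no in-vocabulary GO term are
excluded from training. The training table round-trips through ARFF with
nominal {0,1,2,3} attributes for interoperability with Weka-family
multi-label tools.

## Learning

### Feature ranking (RF-ML)

Multi-label feature selection uses an RReliefF-style accumulation: for each
instance and its `k_nn = 10` nearest neighbors under the Manhattan distance
on range-scaled features, the label dissimilarity (normalized Hamming
distance between label rows) and per-feature value differences are
accumulated, and a feature is weighted by how much its differences co-occur
with label differences versus label agreements. A constant feature can never
score above zero; a duplicated informative feature ties exactly with its
twin (ties break alphabetically). One property of the accumulation deserves
emphasis: when many instances share identical feature rows — as happens by
construction when several proteins of one operon are instances — the nearest
neighbors of an instance are its duplicates, all label dissimilarities among
accumulated pairs can be zero, and every weight collapses to 0 with a
warning. The ranking is then uninformative (order falls back to feature id),
which is the honest answer for such data; the weight formula itself is
verified against an independent naive accumulation on a hand-built fixture.

### Transformations

Three problem transformations share one random-forest base learner
(probability forests; default 100 trees, `mtry = ⌊√p⌋`, explicit seed):

* **BR** (binary relevance): one binary member per label; the label score is
  the member's positive-class probability.
* **LP** (label powerset): one multiclass member over the labelsets observed
  in training; the label score is the summed probability of the classes
  containing it, so scores are automatically coherent marginals.
* **RAkEL**: `m` LP members on distinct random label subsets of size
  `k = 3` (default `m = min(2|L|, C(|L|,k))`), aggregated by mean marginal
  over covering members; a label no member covers scores 0, with a warning.

Every member is fitted with the base-spec seed. This is a deliberate
reproducibility contract: with equal seeds, RAkEL at `k = |L|, m = 1` equals
LP and RAkEL at `k = 1` with full coverage equals BR *exactly*, score matrix
for score matrix — the test suite asserts both identities with zero
tolerance. Degenerate training responses (a single observed class or
labelset) yield constant scorers with warnings rather than errors, so
cross-validation folds that lose all positives of a rare label still run.

A single-label binary mode (photosynthetic / not) is the one-label special
case of BR; its reporting rule flags queries at ≥ 0.8 probability as
high-confidence candidates, with 0.5 as the plain decision threshold.

## Evaluation

F1max follows the CAFA protocol: at each threshold `t` in 0, 0.1, …, 1
(inclusive ≥, so t = 0 predicts every label), precision is averaged over the
m(t) proteins with at least one predicted label, recall over all n proteins,
and F1max is the maximum harmonic mean over the grid. F1(t) is defined as 0
when m(t) = 0, where the precision average is otherwise undefined. The
implementation is checked against a literal transcription of the defining
equations on hundreds of random fixtures, and a hand-enumerated two-protein
example (F1max = 6/7) is pinned as a regression anchor.

Nested cross-validation (5 outer × 3 inner folds, 5 repetitions by default)
tunes the three knobs the model exposes — trees, `mtry` rule, and the number
of top-ranked features retained — maximizing mean inner-fold F1max with ties
going to the first grid row; feature ranking is recomputed inside every
inner training fold so selection never sees evaluation data, and the fold
bookkeeping is exported so leakage can be audited. Folds are shuffled but
not stratified by labelset: with 24 labels most labelsets are rare, and
stratification would mostly reorder singletons; the seed is logged instead.

Paired model comparisons use a two-sided Wilcoxon signed-rank test with zero
differences dropped, the exact signed-rank distribution (midranks under
ties) enumerated for up to 25 nonzero pairs and a normal approximation with
continuity and tie corrections beyond. The exact path matters: per-fold
metric differences are routinely tied, and the reference implementation in
`stats` declines exact computation under ties.

The sequence-only baseline transfers the labels of each query's best
training hit passing an E-value cutoff, scored by percent identity / 100 —
the classical annotation-transfer approach the neighborhood model is
measured against.

## Neighborhood networks and enrichment

For any database protein, the package exports a star-shaped genome
neighborhood network per tier: a hexagonal query node and elliptical
neighbor nodes sized `20 + 60·raw/raw_max` (uniform minimum size when
everything is nonconserved), in Cytoscape-elements JSON and GraphML.
GO enrichment among the neighborhood genes uses the one-sided hypergeometric
upper tail with Benjamini–Hochberg adjustment across tested terms. The
background universe is all GO-annotated proteins in the loaded database, not
the whole gene set — unannotatable genes would otherwise deflate every
p-value; the choice is recorded in the output.

## The synthetic study condition

The simulator generates what the method assumes and nothing more: a
pure-birth genome tree; families assigned to random clades (so gene-content
distances recover the tree); planted operons — by default 12 operons of 4
families on clades covering ~60% of 30 genomes, among 400 families — laid
out with within-operon gaps uniform on 10–200 bp, background gaps uniform on
400–5000 bp, a quarter of operons placed as divergent pairs, and a 10%
per-genome chance that a planted neighbor is relocated; within-family
similarity hits below 1e-120 and cross-family noise above 1e-5, so every
tier recovers families exactly and noise perturbs *placement*, never
*similarity*; and the focal family of each operon annotated with 2 vocabulary
terms. Ground truth (planted pairs, informative feature columns) is emitted
alongside.

Under this default condition the pipeline produces ~215 instances with
~45 feature columns, and pooled 5-fold cross-validation reaches F1max 1.0
for RAkEL while the label-permuted control stays below 0.3 — the signal is
strong by design, because the run validates the machinery, not the biology.
What passing does *not* show: robustness to annotation noise, to partially
correct family clustering, to horizontal transfer, or to the class imbalance
of real annotation databases; the simulator does not model sequence
evolution at all (FASTA output is placeholder). Problem sizes throughout the
test suite (dozens of genomes, hundreds of families) were chosen as the
smallest at which every contract is exercised, including tie and degenerate
cases.

## Numerical choices and edge cases

* Gap thresholds are inclusive at both ends (≤ 250; 200 ≤ gap ≤ 1000).
* Quantile `type = 4`; threshold comparisons in F1max and screening are
  inclusive (≥).
* NJ branch lengths are clamped at 0; a 2-genome tree is a single edge.
* Ties: duplicate hits by (min E, max bitscore); feature ranks by weight
  then feature id; grid search by declared grid order; nearest neighbors in
  RF-ML by distance then row order.
* All randomness (simulation, fold shuffles, subset sampling, forests) flows
  from explicit seeds; two runs with equal configuration and seeds produce
  identical artifacts.
* Degenerate inputs (empty files, header-only tables, single-class labels,
  all-zero scores, fewer than three positive conservation scores) warn and
  continue with documented fallbacks rather than fail.

## Known limitations

The method is intrinsically prokaryotic: it presumes operons and conserved
gene order, and offers nothing for genomes without them. Labels are treated
as flat — no GO-graph propagation or hierarchy-aware classification — so a
prediction of a child term does not imply its parents. Neighborhoods at
contig boundaries are truncated, and circular-origin adjacencies are not
recovered. The conservation score depends on the genome sample: adding many
near-identical genomes changes raw scores little (by design), but adding a
distant clade rescales the tree and hence the quantile bins, so models
should be retrained when the genome collection changes substantially.
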