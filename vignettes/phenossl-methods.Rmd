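---
title: "Methods: self-supervised attributed-network embeddings for gene-phenotype prediction"
author: "phenossl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-supervised attributed-network embeddings for gene-phenotype prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenossl)
```

## The problem

Most human genes have no curated phenotype annotations, so supervised
gene–phenotype predictors starve for labels.  `phenossl` addresses this by
pretraining gene representations *without* phenotype labels, on a gene
attributed network built from two label-free resources: a protein–protein
interaction (PPI) graph and Gene Ontology (GO) annotation indicators.  The
pretrained embeddings then feed a comparatively small supervised multi-label
classifier over phenotype-ontology terms.  The premise is biological:
functionally related genes interact more often, share functional
annotations, and produce similar phenotypes, so a representation that
captures the first two relations transfers to the third.

## Dataset construction

Phenotype and GO annotations live on directed acyclic ontology graphs and
obey the true-path rule: annotating a gene with a term implies annotation
with every ancestor.  `propagate_annotations()` closes each gene's term set
under the ancestor relation.  The label space is then restricted to one
ontology branch (`restrict_to_branch()`; the branch root itself is excluded
by default because after propagation it annotates every remaining gene and
carries no signal), and rarely annotated terms are removed:
`filter_terms_by_count()` drops terms annotating 10 or fewer genes and bins
the survivors by annotated-gene count into the groups `11-30`, `31-100`,
`101-300` and `>300`, which later stratify evaluation.

Count filtering is **single-pass**: counts are computed once, before any
removal.  Removing a term can orphan genes and thereby lower other terms'
counts, but re-iterating the filter would make the final label space depend
on iteration order; a one-shot filter is reproducible and matches partial-
evaluation practice in community benchmarks.  This is a genuinely open
choice and the package's position is recorded here.

## The attributed network

Nodes are genes; the edge set comes from a scored PPI list.  Scores must
arrive in $[0,1]$ (the reader's `string_scale` flag divides raw STRING
combined scores by 1000) and an undirected edge is kept when any duplicate
reaches the threshold, 0.3 by default — low-confidence interactions are
discarded outright rather than down-weighted.  Node attributes are binary
GO-term indicators.  Because that indicator matrix is wide and sparse,
centered PCA (`reduce_dimensions_pca()`, default 1000 components on real
data) replaces it before filtering.  The projection is fit on all genes:
pretraining is transductive, no phenotype labels are involved, so there is
no leakage.  Component signs are fixed by forcing each component's
largest-magnitude loading positive, making results machine-independent.

## Laplacian smoothing filter

With self-looped adjacency $\tilde A = I + A$, degree matrix
$\tilde D = \mathrm{diag}(\tilde A \mathbf 1)$ and the symmetric normalized
Laplacian
$\tilde L_{sym} = \tilde D^{-1/2} (\tilde D - \tilde A) \tilde D^{-1/2}$,
the filter is

$$H = I - \alpha \tilde L_{sym}, \qquad \tilde X = H^t X.$$

$\tilde L_{sym}$ has spectrum in $[0, 2)$, so $H$ damps high-frequency
(neighbour-inconsistent) components while preserving smooth ones; with the
default $\alpha = 2/3$ every eigenvalue of $H$ has magnitude at most 1 and
repeated application is stable.  Self-loops guarantee positive degrees, so
isolated genes are well-defined and pass through unchanged.  `filter$t`
(default 2) controls smoothing depth; it is deliberately exposed because the
optimal depth is data-dependent.  A `laplacian_sign = "plus"` variant
(building $\tilde D + \tilde A$ instead) is available purely for replication
experiments; it inverts the frequency response and anti-smooths, and the
package default is the standard Laplacian.

## Self-supervised pretraining

The encoder is linear, $Z = \tilde X W$, followed by per-column min–max
scaling onto $[0,1]$ (a constant column scales to zero).  Scaling is part of
the encoder: it keeps $Z$ non-negative so that the row-wise cosine
similarity $s_{ij} = \langle z_i, z_j\rangle / (\lVert z_i\rVert \lVert
z_j\rVert)$ lies in $[0,1]$ and can act directly as a probability.

The pretext task (`select_training_pairs()`): rank all unordered gene pairs
by $s_{ij}$; the top $k$ become positives ($y = 1$), the bottom $k$
negatives ($y = 0$), with ties broken lexicographically for determinism.
The loss is the summed binary cross-entropy with $s_{ij}$ as the prediction,

$$L_{self} = -\sum_{(i,j)} \big[y \log s_{ij} + (1-y) \log(1-s_{ij})\big],$$

clamped at $\varepsilon = 10^{-15}$.  Adam updates $W$; pairs are
re-selected every `reselect_every` epochs (default 1) so the supervision
tracks the evolving embedding.  Three choices here were genuinely open and
are fixed as follows:

* **Similarity convention** — similarities are computed on the scaled
  embedding and the *same* values are used for selection and for the loss;
  one consistent convention keeps the loss well-defined in $[0,1]$.
* **Gradient through scaling** — the per-column min and range are treated
  as constants within each step (a stop-gradient).  The alternative
  (differentiating through the extrema) makes single entries' gradients
  dominate whole columns and destabilizes training.
* **$k$** — defaults to $10n$ pairs (capped at half the pair count).  There
  is no principled universal value; $10n$ keeps the selected set a small,
  high-confidence fraction of all $\binom n2$ pairs at benchmark sizes.

The full $n \times n$ similarity matrix is materialized, which bounds
practical problem size at a few tens of thousands of genes (a guard errors
above 20 000 rather than thrash memory); that covers the gene universes
this method targets.

## Multi-label classifier

Embeddings feed a dense network with three hidden layers (affine → batch
normalization → LeakyReLU, slope 0.01) and a sigmoid output unit per
phenotype term, trained with Adam (batch 128, learning rate 0.001) on the
mean multi-label binary cross-entropy.  Mean rather than summed reduction
differs only by a constant factor and keeps the learning rate meaningful
across label-space sizes.  Hidden widths default to 1024/512/512; widths
are data-scale parameters, not method constants, and the scaled-down
benchmark uses proportionately smaller ones (below).  Training holds out
10% of training genes for early stopping (patience 20, best weights
restored).  Batch-norm inference uses running statistics, so a gene's
prediction is independent of batch composition — asserted to $10^{-6}$ in
the tests.  Any scorer mapping embeddings to $[0,1]^q$ can stand in for the
DNN, which keeps classifier comparisons orthogonal to the representation.

## Evaluation protocol

`term_aupr()` computes average precision with tie-aware block handling (no
trapezoidal interpolation, which is optimistic for PR curves).  Fmax scans
thresholds $\{0, 0.01, \dots, 1\}$.  Macro variants average per-term values
over terms with at least one positive; micro variants flatten the
gene-by-term matrix first.  Macro-Fmax uses the per-term optimal threshold
by default; a shared-threshold variant (`macro_shared = TRUE`) is provided
because both readings of "average then maximize" exist in practice, and the
tests pin both against brute-force enumeration.  Terms without test
positives are excluded (their AUPR is undefined — a sentinel, never a
silent zero).  Splits: seeded 5-fold CV (`make_cv_splits()`, round-robin
after shuffling) in which each gene is scored by the model that held it
out, and a temporal split (`make_temporal_split()`) whose test set is
exactly the genes with no annotations at the earlier snapshot and at least
one at the later snapshot.

## Synthetic benchmark

`simulate_dataset()` draws from a stochastic block model in which one
latent block assignment drives all three data channels: topology
(within-block edge probability 0.2 vs 0.02 across blocks), attributes
(each binary column "belongs" to a block and activates at 0.30 there vs
0.15 elsewhere), and labels (each term links to one or two blocks and
annotates their genes at 0.6 vs 0.05 elsewhere, then 2% of cells are
flipped).  Defaults: 300 genes, 3 blocks, 60 attributes, 20 terms, seed 17.

The attribute channel is deliberately *weaker* than the label channel:
individually weak indicator columns under-determine the blocks, so graph
topology carries information the attributes alone do not — precisely the
regime the method is designed for.  If attributes alone pinned down the
blocks, every pipeline variant would saturate at the label-noise ceiling
and component comparisons would measure nothing.

What the generator does **not** emulate: real degree and annotation-count
distributions (both heavy-tailed in STRING/HPO), ontology depth (the
emitted fixture ontology is flat), annotation evidence codes, and
correlated annotation noise.  Passing the benchmark therefore demonstrates
mechanism — signal recovery through smoothing, pretraining and
classification — not real-data performance.

Scaled-down study sizes: the benchmark runs with 50 PCA components, 256-dim
embeddings, 150 pretraining epochs and 128/64/64 hidden layers
(`benchmark_config()`), proportionate to its 60 attribute columns and 300
genes.  On this benchmark the filtered-and-pretrained pipeline lifts
held-out macro-AUPR from roughly 0.40 (PCA features alone) to roughly 0.55,
against a matched-prevalence no-signal baseline near 0.30; the exact values
for any seed are recomputed by `scripts/acceptance.R` and the acceptance
tests, and no number quoted here is asserted anywhere the code does not
compute it.

## Numerical choices and degenerate inputs

* Ties in pair ranking and in PR curves are handled deterministically
  (lexicographic pair order; block-averaged precision).
* Constant embedding columns scale to zero; all-zero embedding rows get
  similarity 0 to everything and are excluded from gradients.
* Similarities are clamped to $[10^{-15}, 1-10^{-15}]$ in the loss and to
  $[10^{-7}, 1-10^{-7}]$ in gradients; batch-norm adds $10^{-5}$ to
  variances.
* PCA rank deficiency truncates the output width with a warning rather
  than returning noise components.
* A term with zero positives in a training fold warns and trains
  all-negative; a term with zero positives in a test scope is excluded
  from that scope's metrics.
* One run seed fans out to fixed per-stage offsets, so stages can be
  re-run in isolation and two runs with one seed are byte-identical.

## Known limitations

* The min–max-scaled, non-negative embedding bounds cosine similarities
  away from zero in practice (vectors share the positive orthant), which
  limits the contrast the pretext task can create from weak attributes
  alone; the smoothing filter supplies most of the separation on the
  synthetic benchmark, and the pretraining-only variant's advantage over
  raw PCA features is small there.
* PCA is transductive over the full gene universe; inductive prediction
  for genes unseen at pretraining time is out of scope.
* No hierarchical-consistency post-processing is applied to predictions,
  so a child term can out-score its ancestor.
* Dense similarity limits the gene universe to ~20 000 genes.
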