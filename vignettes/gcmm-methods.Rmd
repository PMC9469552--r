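---
title: "Methods: multi-view graph convolutional matrix completion for drug-disease association prediction"
author: "gcmm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-view GCN matrix completion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Drug repurposing asks which approved drugs might treat diseases they were
not developed for. The guilt-by-association premise is that functionally
similar drugs tend to treat similar diseases, so the prediction problem can
be posed on a heterogeneous network: two node families (drugs, diseases),
several intra-family similarity graphs, and a sparse bipartite matrix of
experimentally verified drug-disease associations whose missing entries we
want to score.

# The heterogeneous network

Four similarity views are computed from raw inputs:

* **Chemical (`C`)**, drug side. With $a$ and $b$ bits set in two drugs'
  MACCS-style substructure fingerprints and $c$ bits set in both, the
  Tanimoto coefficient is
  $G^C_{ij} = c / (a + b - c) \in [0, 1]$.
* **Therapeutic (`T`)**, drug side. Each drug has a set of protein targets
  with known amino-acid sequences. Pairwise target similarity is the
  Smith-Waterman local-alignment score normalized by the geometric mean of
  the self-alignment scores,
  $T(e_1, e_2) = SW(e_1, e_2) / \sqrt{SW(e_1, e_1)\,SW(e_2, e_2)}$,
  and $G^T_{ij}$ is the mean of $T(e_1, e_2)$ over all cross pairs
  $e_1 \in E_i$, $e_2 \in E_j$ with $e_1 \ne e_2$ (identical target
  tokens are skipped; an empty pair set scores 0).
* **Semantic (`M`)**, disease side. Diseases live in an ontology DAG. The
  contribution of node $n$ to disease $s$ is $F_s(s) = 1$ and
  $F_s(n) = \Delta \cdot \max\{F_s(n') : n' \text{ child of } n\}$ over the
  ancestor closure $N(s)$; the semantic value is
  $DV(s) = \sum_{n \in N(s)} F_s(n)$ and
  $$G^M_{ij} = \frac{\sum_{n \in N(s_i) \cap N(s_j)}
    \big(F_{s_i}(n) + F_{s_j}(n)\big)}{DV(s_i) + DV(s_j)}.$$
  The default decay is $\Delta = 1$ (every ancestor contributes 1, the
  literal recursion above); $\Delta = 0.5$, the common convention in the
  ontology-similarity literature, is available as a parameter.
* **Target (`A`)**, disease side. Jaccard similarity of the diseases'
  target sets, $|E_i \cap E_j| / |E_i \cup E_j|$.

Degenerate cases are resolved by an identity convention: two all-zero
fingerprints (or two empty target sets) are identical objects and score 1,
a zero object against a non-zero one scores 0. These are $0/0$ cases the
formulas leave undefined; the convention is stated here so the matrices are
reproducible bit for bit.

All matrices are computed on the upper triangle and mirrored, which
enforces exact symmetry against floating-point drift. Diagonals are 1 for
the `C`, `M` and `A` views; the `T` diagonal is *computed* under the
$e_1 \ne e_2$ exclusion (a drug with a single target has therapeutic
self-similarity 0), documented rather than forced.

## Alignment scoring

The underlying local alignment is computed by `Biostrings::pairwiseAlignment`.
No substitution matrix or gap penalties are inherent to the method, so the
package defaults to the community-standard protein settings — BLOSUM62,
gap opening 10, gap extension 1 — configurable via `alignmentParams()`. A
gap of length $k$ costs $\mathrm{open} + k \cdot \mathrm{extend}$. The test
suite validates the raw scores against an independent affine-gap
(Gotoh three-matrix) dynamic program.

# The model

Let $G$ be one view's similarity matrix, used directly as a weighted
adjacency. With self-loops $\tilde A = I + A$ and degree matrix
$\tilde D_{ii} = \sum_j \tilde A_{ij}$, the propagation operator is the
symmetric normalization $L = \tilde D^{-1/2} \tilde A \tilde D^{-1/2}$.
Each view gets its own GCN stack,

$$X^{(l+1)} = \sigma\!\big(L\, X^{(l)} W^{(l)}\big), \qquad \sigma = \mathrm{ReLU},$$

applied to a family-shared random initial feature matrix $X^{(0)}$
(uniform $[0,1)$, fixed, non-trainable by default — the method only states
random initialization, and fixed inputs keep runs reproducible). Two
layers are the default; one layer under-propagates and three over-smooth.

**Channel attention.** Each family has two view channels. Global average
pooling collapses each view embedding to a scalar statistic
$z = \mathrm{mean}(X)$; the channel weights are the squeeze-and-excitation
gate $Z_{att} = \mathrm{sigmoid}(W_2\, \mathrm{ReLU}(W_1 Z))$, strictly in
$(0,1)$, and each view embedding is rescaled by its scalar weight. No
further normalization is applied — the fusion is exactly scalar
reweighting followed by column-wise stacking. With zero attention
parameters every gate is $\mathrm{sigmoid}(0) = 0.5$, which the tests use
as an exact reduction to the no-attention variant.

**Extractor.** The stacked channels (nodes × 2F) pass through a fully
connected layer with one independent linear unit per output channel:
$X' = \mathrm{ReLU}(W\, \tilde X^\top + b) \in
\mathbb{R}^{F_{out} \times N}$. Written this way the output has the
declared $F_{out} \times N$ shape; a reading where a single unit is reused
for all output channels cannot produce it.

**Decoder and loss.** Association scores are inner products,
$U = X'^\top Y'$, and training minimizes the squared Frobenius
reconstruction error $\lVert U - U' \rVert_F^2$ restricted to the training
pairs. The mask reconciles the whole-matrix objective with the evaluation
protocol, which trains on sampled positives plus an equal number of
sampled negatives; a full-matrix mode (the `all_pairs` regime) is
available.

**Optimization.** Full-batch Adam (defaults: 1000 epochs, learning rate
0.001, $\beta_1 = 0.9$, $\beta_2 = 0.999$). Gradients are derived in
closed form by reverse-mode differentiation of the block composition and
are checked against central finite differences in the test suite for all
three architectural variants. All weights are Glorot-uniform at
initialization, drawn from a single seeded stream so a (sizes, config,
seed) triple fully determines the run.

## Dense graphs and top-k sparsification

Similarity graphs are near-complete: almost every pair has a positive
weight. After symmetric normalization, two propagation hops then average
features over essentially the whole graph, and node embeddings collapse
toward a common value (the over-smoothing regime), which slows training
dramatically on small dense instances. `gcmmConfig(adjTopK = k)` keeps each
node's k strongest neighbours (re-symmetrized by maximum) before
normalization. The default is the dense operator; the synthetic benchmark
uses `adjTopK = 10`.

# Evaluation protocol

`makeCvPlan()` partitions the known associations into k folds (default 5)
and samples an equal number of negatives uniformly without replacement
from the zero cells (the `balanced` regime; negatives are fixed per plan,
not re-sampled per epoch). Per fold, the model trains on the other folds'
pairs and scores the held-out pairs.

Ranking metrics: ROC-AUC via the Mann-Whitney rank statistic with ties
averaged, and AUPR by step-wise integration (precision held between recall
points, tied scores processed as a block) — stepwise rather than
trapezoidal because linear interpolation in PR space overstates the area.
Threshold metrics (precision, recall, accuracy, F1, specificity) need a
decision threshold on unbounded inner-product scores; the package min-max
scales scores within each validation fold and thresholds at 0.5 by
default, with an F1-maximizing threshold as an option. The true-positive
rate is $TP / (TP + FN)$ throughout — the standard ROC definition,
consistent with the recall definition used by the same protocol.

Ablations: `no_att` replaces the attention gate with unit weights;
`no_lin` bypasses the extractor and averages the reweighted channels into
the final features; view subsets drop similarity matrices and shrink the
attention channel count. `sweepHyperParams()` grids one of layers /
embedding size / output channels / learning rate with everything else
fixed. `repeatCV()` re-runs the whole protocol under distinct seeds and
reports mean ± sd (default one repeat, since repeats multiply cost).

# The synthetic benchmark

`generateSynthetic()` plants matched drug/disease clusters: cluster
prototypes for fingerprints (bits flipped at rate 0.1 within clusters),
cluster-pooled targets with point-mutated peptide prototypes (so
Smith-Waterman similarity is higher within clusters), one ontology branch
per cluster under a shared root, and a cluster-diagonal association matrix
with 5% of cells flipped as noise. Defaults: 100 drugs, 60 diseases, 40
targets, 5 clusters, fingerprint length 166, peptide length 80, seed 0.
These sizes keep a full 5-fold benchmark around a minute on one CPU while
leaving every similarity view informative.

`runSyntheticBenchmark()` is the one-call harness: 5-fold balanced CV, 300
epochs, embedding 64, 32 output channels, `adjTopK = 10`, learning rate
0.001. The narrower-than-default model and shorter-than-default training
match the benchmark's problem size; the package defaults (256/128/1000)
remain the recommended settings for realistically sized networks. The test
suite asserts mean held-out AUC at or above 0.85, a final-to-initial
training-loss ratio below 25% (as the mean over the five folds — single
folds fluctuate because the flipped cells set a noise floor that can only
be beaten by memorizing individual noise cells), and that the full model
is within 0.02 AUC of never being outperformed by its two ablations.

What the generator does **not** emulate: realistic chemistry (fingerprint
bits are exchangeable Bernoulli draws, not substructure keys), ontology
depth and fan-out of real disease vocabularies, realistic association
sparsity (the planted blocks are much denser than curated databases), or
target promiscuity across clusters. Passing the benchmark therefore shows
the machinery recovers planted multi-view structure — it does not certify
performance on any real drug-disease corpus.

# Numerical and design notes

* Joins between matrices and registries are by id token, never by
  position; misaligned inputs are rejected, not reindexed.
* Disease records whose ontology term is missing from the DAG fail at
  load; silently dropping them would skew the disease count.
* File dialect: UTF-8 TSV with header; matrix files carry ids in the first
  row/column and similarity files a `# view:` tag; doubles are written as
  `%.17g`, which round-trips exactly.
* Ties in `predictTopK()` are broken by drug id order, so ranked lists are
  deterministic.
* `withSeed()` snapshots and restores the caller's RNG state, so package
  functions never perturb user-level randomness.
* Whether the initial features should be trainable is genuinely open; the
  package fixes them (reproducibility, fewer parameters) and exposes the
  weights only. GCN layers carry no bias, matching the stated propagation
  rule.

# Limitations

Training is full-batch dense linear algebra: memory scales as
$O(N_g^2 + N_s^2)$ and the intended scale is thousands of nodes, not
millions. The package ships no public-database parsers or id
normalization (inputs are expected in the documented dialects with
consistent tokens), and no fingerprint computation beyond an optional
user-supplied SMILES callback. Baseline architectures from the
surrounding literature are out of scope.
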