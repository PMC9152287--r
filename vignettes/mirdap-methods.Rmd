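---
title: "Predicting disease-associated miRNAs from network embeddings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting disease-associated miRNAs from network embeddings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Only a small set of miRNAs is annotated as associated with a given disease
(here, the motivating case is multiple sclerosis); everything else is
*unlabeled*, not known-negative. `mirdap` implements a guilt-by-association
prediction framework for this positive-unlabeled setting. Two miRNA networks
carry the association signal:

* a **functional-similarity network** — a symmetric matrix of MISIM-style
  similarity scores in [0, 1], treated as a weighted undirected graph;
* a **miRNA–mRNA interaction network** — a bipartite edge list
  (mirTarBase-style) walked as a single homogeneous unweighted graph over
  miRNA and gene nodes.

The premise is that miRNAs with similar functions, or with overlapping
target programs, tend to associate with the same disease. The framework
turns network position into features and hands them to a classifier.

## Stage 1: node embeddings

Each network is embedded separately with second-order biased random walks
followed by skip-gram. A walker at node $c$ that arrived from $t$ steps to
neighbor $x$ with probability proportional to $w(c,x)\,\alpha(t,x)$, where
$\alpha = 1/p$ if $x = t$, $1$ if $x$ is adjacent to $t$, and $1/q$
otherwise. The package defaults are $p = 10$, $q = 0.5$: walks rarely
backtrack and lean depth-first, which emphasizes community structure
(homophily). $p = q = 1$ recovers the unbiased weight-proportional walk
(the DeepWalk special case, available via `embedder = "deepwalk"`).

Skip-gram learns an encoder $f(u) \in \mathbb{R}^d$ maximizing
$\sum_u \log P(N_S(u) \mid f(u))$, i.e. minimizing
$\mathcal{L} = \sum_u \sum_{v \in N_S(u)} -\log P(v \mid f(u))$ with
$P(v \mid f(u)) = \exp(f(u)^\top f(v)) / \sum_n \exp(f(u)^\top f(n))$.
Production training approximates the softmax with negative sampling (5
negatives from the unigram$^{3/4}$ distribution, SGD with a linearly
decaying rate); the exact softmax is implemented separately
(`skipgram_softmax_loss()`) purely as a diagnostic oracle, and the test
suite checks that it decreases over training epochs on small graphs.

Walk and training defaults follow the reference node2vec/word2vec settings:
10 walks per node, walk length 80, window 10, 5 negatives, initial rate
0.025, and **one** SGD pass over the corpus — the reference node2vec
implementation's default; the corpus already visits every node ten times,
so a single pass is one full effective epoch of each node's neighborhood.
Input vectors start uniform in $[-0.5/d, 0.5/d]$, context vectors at zero.
All of these are overridable in `skipgram_config()` / `walk_config()`.

Per network the embedding dimension is $d = 512$; the two blocks are
concatenated into a 1024-d feature row per miRNA. A miRNA present in only
one network gets exact zeros in the other block (recorded by presence
flags); gene vectors are learned but discarded. Nodes of a network are
matched across sources case-insensitively after trimming whitespace, with
no precursor/mature mapping — identifiers must match as given.

## Stage 2: CNN feature encoder

The encoder follows the printed architecture exactly: 16 one-dimensional
convolution kernels of size 1×3 with 'same' zero padding (a width-1024
input yields a 16×1024 map), a ReLU fully connected hidden layer of the
same 16×1024 size, max-pooling 1×2 with stride 2 (16×512), a linear FC
layer to the 256-d *code*, then — during training only — dropout at 50%, a
linear FC to 2 and a softmax head trained by mini-batch backpropagation.

Two genuinely open design points and how they were resolved:

* **The 16×1024 hidden layer.** "Same neuron size as the conv output"
  admits two readings. The default here is a *position-shared channel mix*:
  one 16×16 weight matrix (plus bias) applied at every position, the 1×1
  convolution idiom. A fully dense 16,384→16,384 map is the more literal
  reading but carries 2.7×10⁸ parameters against a few hundred training
  rows — two orders of magnitude more parameters than the rest of the
  network combined — and is statistically and computationally
  disproportionate at this sample size; it remains available via
  `fc_hidden = "dense"`.
* **Training hyperparameters** are stated nowhere, so they are declared
  package defaults: Adam at 1e-3, batch size 32, up to 100 epochs with
  early stopping when the epoch training loss plateaus (relative
  improvement below 0.1% for 5 consecutive epochs) or effectively vanishes
  (cross-entropy below 1e-3). Inverted dropout keeps evaluation-time
  activations unscaled.

At prediction time dropout is off and the 256-d code — the output of the
first linear FC layer — is extracted; `encode()` is a pure function of its
input. The three ablation variants each remove exactly one named layer
(ReLU FC, pooling, or convolution) while keeping the 256-d code and the
head; with the convolution removed the hidden layer becomes a dense
width×width ReLU map, since a one-channel channel-mix would be a scalar
rescaling.

Class convention: index 1 is "disease-associated". Features enter the
encoder raw (no standardization), matching the embeddings-as-features
design; `standardize = TRUE` enables z-scoring.

## Stage 3: Gaussian naive Bayes

The final classifier is Gaussian naive Bayes over the codes, with the
standard defaults: class-frequency priors, per-class maximum-likelihood
moments, and variance smoothing $\varepsilon = 10^{-9} \max_j
\widehat{\mathrm{Var}}(x_j)$ added to every variance. Posteriors are
computed in log space with log-sum-exp, so rows are finite, normalized,
and shift-invariant. The classifier stage sits behind a small
fit/predict interface so alternatives can be slotted in externally, but
only GaussianNB ships.

## Evaluation protocol

Negatives are drawn uniformly without replacement from the unlabeled pool
at `ratio` × (number of positives), or `"all"` takes the whole pool;
sampling happens once per experiment, not per fold. Cross-validation is
stratified five-fold (plain five-fold with ~100 positives against
thousands of negatives can produce folds without positives). Per fold the
encoder is trained on the training split only, both splits are encoded,
GaussianNB is fitted on training codes and the held-out miRNAs are scored.

Embeddings are computed **once per dataset**, not per fold: labels play no
role in the unsupervised embedding stage, so there is no leakage; this
mirrors using one fixed feature table across all experiments.

Metric conventions (they move third-decimal results, so they are fixed and
tested):

* ROC-AUC is the Mann–Whitney probability with ties counted 0.5 —
  equivalently the trapezoidal ROC area.
* PR-AUC is the average-precision summation
  $\sum_k (R_k - R_{k-1}) P_k$ over descending score thresholds with tied
  scores collapsed — the standard AP estimator, deliberately *not* the
  trapezoidal PR interpolation, which is known to be optimistic.
* F1 uses hard labels at posterior ≥ 0.5 (the classifier's own decision
  rule) and is defined as 0 when precision + recall is 0.
* Curve plots interpolate each fold onto a fixed 101-point FPR (or recall)
  grid and show the mean ± one standard deviation across folds.

Candidate ranking trains on all labeled data (positives plus sampled
negatives), scores every non-positive miRNA, sorts by positive-class
posterior and breaks ties lexicographically by id.

## The synthetic benchmark

Real MISIM/HMDD/mirTarBase releases cannot be bundled, so the generator
plants exactly the structure the method assumes: positives form a
similarity community (block mean `sim_within = 0.6` vs background 0.15,
symmetric Gaussian noise sd 0.05, clipped to [0, 1], unit diagonal) and
share targets (each of 40 targets drawn from a 200-gene shared pool with
probability 0.7). The default scale mimics the real resources: 500
miRNAs, 100 positives, 2000 genes, and 10% of miRNAs present in only one
network so zero-padding is exercised. Identifiers follow realistic
patterns (`hsa-miR-synth-N`, `G000001`) and the generator writes the same
three file formats the readers parse.

What it does *not* emulate: the heavy-tailed degree distributions of real
interaction data, evidence-type heterogeneity, precursor/mature id
ambiguity, and correlated noise between the two networks. Passing tests
therefore demonstrate that the machinery recovers a planted
guilt-by-association signal and respects the published protocol — not that
real-data performance numbers are reproduced.

One consequence of the chosen scale: with 100 positives and only 400
unlabeled miRNAs, negative ratios above 4 are infeasible without
replacement (the same arithmetic tension exists in the real data, where 50
× 102 exceeds the unlabeled pool). `sample_negatives()` treats an
oversized request as a configuration error, and the negative-ratio trend
is therefore evaluated on a taller generator configuration (820 miRNAs, 15
positives, identical signal parameters) where every ratio up to 50 is
well-defined.

## Determinism and numerics

All randomness flows from explicit integer seeds through a platform-
independent splitmix64 generator in the compiled core (walks, negative
sampling, initialization, shuffling, dropout) or through R's RNG with
save/restore semantics, so identical seeds reproduce walks, embeddings,
encoders and reports bit-for-bit in single-threaded runs. The compiled
core uses single precision (the word2vec convention) with losses
accumulated in double precision; analytic gradients are verified against
central finite differences to 1e-4 relative. Degenerate inputs are
handled explicitly: isolated nodes produce no walks and end distributions,
zero-weight similarity pairs are absent from the walk graph (a zero
transition probability either way), constant features survive through
variance smoothing, and all-tied scores give ROC-AUC 0.5.

## Problem sizes in the test suite

The structural and oracle tests run on toy instances (graphs of 2–30
nodes, feature widths 16–64). The end-to-end properties — signal
recovery, the negative-ratio trend, the network-combination comparison,
and the layer ablations — run on the full 500-miRNA benchmark (and the
820-miRNA ratio-sweep variant) with three experiment seeds per
configuration, the embedding computed once per dataset. These sizes are
the package's chosen benchmark conditions; the generator's signal
parameters are never varied between checks.

## Known limitations

* The PU protocol treats sampled unlabeled miRNAs as negatives; reported
  PR-AUC/F1 therefore depend strongly on the chosen ratio (that dependence
  is itself one of the tested behaviors).
* The synthetic benchmark's planted signal is strong; on it the full model
  and its ablations can all sit near ceiling, so ablation comparisons are
  directional, not effect-size estimates.
* Only binary classification is supported, and only GaussianNB ships as
  the final stage.
* Embedding once on the full network is standard for transductive node
  classification but means feature vectors have seen the *structure*
  (never the labels) of test-fold miRNAs.
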