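---
title: "Methods: graph-based anticancer peptide classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-based anticancer peptide classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`acpgcn` classifies peptides as anticancer (ACP) or not from sequence
alone. A peptide of length $n$ is represented as a path graph: one node per
residue, undirected edges between chain neighbours, so the adjacency $A$ is
symmetric, binary, zero-diagonal with exactly $2(n-1)$ nonzero entries.
This is the minimal structural assumption — edges encode the peptide bond
chain and nothing else (no predicted secondary structure, no spatial
contacts). Each node $i$ carries a label in $1..20$ (the residue's rank in
the alphabet A, C, D, E, F, G, H, I, K, L, M, N, P, Q, R, S, T, V, W, Y)
and an attribute vector concatenating up to four encodings, in the fixed
order:

1. **One-hot** (20 dims): indicator of the residue identity at the
   alphabet rank, so the node label always equals the position of the 1.
2. **node2vec** (default 16 dims): skip-gram embeddings trained on biased
   random walks over this peptide's own graph. Because the walk process
   sees only graph structure, the embedding of a chain depends only on its
   length — it is a *learned positional encoding*, complementary to the
   residue-identity channels. `featurize_dataset()` exploits this by
   caching embeddings per length, which is bit-identical to embedding every
   record separately (each call reseeds the generator).
3. **Ten-property binary encoding** (10 dims): membership bits for
   aromatic, negative, positive, polar, hydrophobic, aliphatic, tiny,
   charged, small, and proline groups. Residues may be members of several
   groups (histidine is aromatic, positive, polar, hydrophobic and
   charged).
4. **CTD encoding** (21 dims): seven physicochemical properties
   (hydrophobicity, normalized van der Waals volume, polarity,
   polarizibility, charge, secondary structure, solvent accessibility),
   each partitioning the 20 residues into three groups; exactly one group
   bit is set per property, so every vector sums to 7. The group tables are
   stored verbatim in `R/encoders.R` and asserted to be partitions in the
   test suite.

The network has three branches over the node-attribute matrix $X$ and
adjacency $A$, fused by a head $F(X) = L(G(X) \,\|\, D(X) \,\|\, R(X))$:

* **Stacked GCN branch $G(X)$.** Each layer computes
  $H^{(l+1)} = \sigma(\tilde D^{-1/2} \tilde A \tilde D^{-1/2} H^{(l)} W^{(l)})$
  with $\tilde A = A + I$ and $\tilde D$ its degree matrix
  ($\sigma$ = ReLU). Self-loops guarantee strictly positive degrees, so
  single-residue "graphs" and isolated nodes are well defined. After
  `n_layers` layers the node features are reduced to one graph vector by a
  permutation-invariant readout (mean by default; sum and max available).
* **Graph-collapse pooling branch $D(X)$.** Each pooling step runs two
  independent three-layer GCN stacks on the current graph: an embedding
  stack $Z = G_{embed}(A, H)$ and an assignment stack whose row-softmax
  gives a soft cluster-assignment matrix $S$ (rows sum to 1). Features and
  structure coarsen as $Z' = S^\top Z$ and $A' = S^\top A S$; the coarsened
  adjacency is renormalized (with self-loops) before the next step, and the
  renormalization is differentiated through during training. After the
  learned steps, a final three-layer embedding stack runs and the
  assignment is *fixed* to the all-ones column, collapsing the remaining
  clusters into one supernode whose feature vector is the branch output.
* **Residual branch $R(X)$.** A linear projection takes the input
  attributes to the hidden width, then each layer adds an identity skip:
  $H_{l+1} = \mathrm{gcn}(H_l) + H_l$, followed by the readout and a linear
  map to the output width. The skips keep the gradient norm at early layers
  from collapsing in deep stacks (asserted empirically in the tests).

The head concatenates the enabled branch vectors, applies two fully
connected layers (to `hidden_dim` with ReLU, then to 2) and a softmax.
Training minimizes the mean binary cross-entropy with Adam.

### Label convention

Datasets store ACP as label **0** and non-ACP as label **1**, and the model
head emits probabilities in that slot order. All metrics nevertheless treat
ACP as the positive class; the inversion happens in exactly one place
(`confusion_counts()` / the loss's documented orientation), so SE, SP,
precision, ACC, MCC, F1 and AUC all read conventionally.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `hidden_dim`, `out_dim` | 64, 64 | width of GCN layers and of each branch's graph vector |
| `n_layers` | 3 | depth of the G and R branches. Chains of 10–50 residues need few message-passing rounds, and deep unskipped stacks oversmooth a path graph; the sweep harness covers depths 5–10 |
| `assign_ratio` | 0.5 | multiplicative cluster shrink per pooling step, sweepable over 0.3–0.9; 0.5 halves the graph each step and reaches a handful of clusters in two steps for typical chain lengths |
| `n_pool_steps` | 2 | learned pooling steps before the all-ones collapse |
| `readout` | mean | permutation-invariant; mean keeps outputs on a length-independent scale |
| `fusion` | concat | `‖` is implemented literally; `mean` and `sum` fusion are available as options |
| `dropout` | 0 | optional, applied to the head's hidden layer during training |
| `max_nodes` | 50 | chain length the pooling weights are sized for (upper end of typical ACP lengths) |
| `epochs`, `learning_rate`, `batch_size` | 1000, 0.01, 32 | training defaults; the sweep harness covers learning rates 0.1 / 0.01 / 0.001. Tests and the acceptance script use far fewer epochs (see below) |
| node2vec `dim, walks, walk length, window, p, q, epochs` | 16, 10, 20, 5, 4, 0.25, 5 | `p > 1, q < 1` biases walks depth-first along the chain so embeddings are local in chain distance (asserted in the tests); walk length is capped at the chain length |

## Design choices where the design was open

* **Readout for $G(X)$ and $R(X)$**: mean pooling, the minimal assumption
  that preserves permutation invariance; exposed as configuration.
* **node2vec scope**: trained per peptide graph, not on a pooled graph of
  the whole dataset — the graph unit of the method is a single chain.
  Consequence: it encodes position/length, not residue identity.
* **Pooling cluster schedule and weight sharing**: cluster counts follow
  $n_{l+1} = \max(1, \lceil \texttt{assign\_ratio} \cdot n_l \rceil)$ per
  graph. Because the assignment stack's output width *is* the cluster
  count, its last weight matrix is sized for the schedule at `max_nodes`
  and column-sliced per graph, so weights are shared across peptides of
  different lengths while honouring the per-graph schedule.
* **Residual attachment**: $R(X)$ is an independent branch with identity
  skips per layer and a first-layer linear projection to reach the hidden
  width.
* **Batching**: graphs are processed one at a time and gradients
  accumulated over the mini-batch — mathematically identical to padded
  batching with node masks, without the padding bookkeeping.
* **Loss sign and sensitivity formula**: the loss is the conventional
  nonnegative mean binary cross-entropy, and sensitivity is
  $TP/(TP+FN) = TP/P$ (the only definition consistent with recall).
* **Pooling regularizers**: auxiliary link-prediction/entropy objectives
  common in differentiable-pooling implementations are off; the training
  objective is pure cross-entropy.
* **Optimizer**: Adam with standard moments; a plain SGD option exists.
* **Decision threshold** 0.5 on the ACP probability; AUC is computed from
  the continuous probability as the Mann–Whitney rank statistic (ties count
  one half).

## Numerical choices and degenerate inputs

* Probabilities are clamped to $[10^{-12}, 1-10^{-12}]$ inside the loss;
  softmaxes subtract the row maximum before exponentiating.
* Metrics with a 0/0 ratio (e.g. precision with no predicted positives,
  MCC with an empty margin) are reported as 0 and flagged in the report's
  `degenerate` field rather than raising — imbalanced ratio designs can
  legitimately produce them.
* Non-standard residues (B, J, O, U, X, Z) are rejected with the record id
  and offending letter; a `drop_invalid` option skips such records with a
  message instead. All encoders are defined only on the 20 standard
  letters.
* Weight initialization is Glorot-uniform from the model seed; every
  stochastic component (generator, walks, initialization, shuffling, fold
  assignment, subsampling) runs under its own locally-scoped seed, so
  results are reproducible end-to-end and independent of the caller's RNG
  state.
* Gradients come from a small reverse-mode tape over dense matrix
  operations (`R/autodiff.R`); the tape forward is asserted equal to the
  plain numeric forward, and tape gradients are checked against central
  finite differences. The node2vec walk/skip-gram inner loops are in C++
  (Rcpp) using R's RNG for determinism.

## The synthetic generator: what it emulates and what it does not

`synth_config()` produces labelled random peptides with uniform lengths in
10–50 (the typical ACP length range). Positives carry a planted cationic
motif (default `KWKLFKK`, present with probability `motif_rate`, default 1)
and a composition bias tripling the sampling weight of K, R, F and W —
echoing, coarsely, the cationic amphipathic chemistry of real ACPs. This
plants signal in both the order-sensitive channels (message passing over
the chain) and the composition-sensitive channels (one-hot and the two
physicochemical encodings). With `motif_rate = 1` a trivial substring
detector achieves perfect accuracy (`motif_baseline()`), which bounds any
model from above and makes the end-to-end recovery test well-posed.

What passing on this benchmark shows: the full pipeline — featurization,
three branches, pooling algebra, gradients, optimization, evaluation —
can learn a recoverable sequence rule from a few hundred peptides.
What it does not show: performance on real ACP data, whose signal is far
weaker, noisier and not reducible to one motif plus composition. The
generator makes no attempt to mimic real ACP physicochemistry beyond the
coarse bias, and headline accuracies on it are near-perfect by design.

## Problem sizes used by the tests and acceptance script

The test suite and `scripts/acceptance.R` run the full model on a
100+100-peptide benchmark with a stratified 9:1 split, trained for 60
epochs (held-out accuracy and MCC are required to reach 0.9/0.8 within a
200-epoch budget); cross-validation uses 5 folds at 20 epochs, and the
ablation (G, G+R, G+D, G+D+R) and ratio (1:1, 1:5, 1:10) designs run at 12
epochs with a narrower network. These sizes are the package's own choice of
a small, fully reproducible study; the defaults (`epochs = 1000`, 250+250
training peptides, an 82 vs 2628 independent test) describe the full-scale
design the harnesses support.

## Known limitations

* The chain graph carries no long-range structural information; residues
  distant in sequence but close in space are never connected.
* Per-peptide node2vec embeddings cannot transfer information across
  peptides; they are positional only.
* Training is CPU-bound, single-threaded R plus BLAS; the implementation
  targets datasets of hundreds to a few thousand peptides, not
  proteome-scale screens.
* The model is a binary classifier; it does not rank by anticancer potency
  or predict mechanism.
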