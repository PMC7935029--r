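---
title: "Connectivity-based graph convolution for frame-wise fMRI classification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based graph convolution for frame-wise fMRI classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cgcn)
```

## The model

`cgcn` classifies ROI-level resting-state fMRI recordings frame by frame on a
graph defined by functional connectivity rather than by spatial adjacency.
The pipeline is:

1. **Functional connectivity.** For every training record (one
   subject-session, a T x N matrix of frames by ROIs), `compute_fc()` forms
   the N x N Pearson correlation matrix; `group_fc()` averages the
   individual matrices entrywise into a group FC matrix. Graphs are always
   built from *training* records only — the cross-validation harnesses
   enforce this.
2. **k-NN graph.** `build_knn_graph()` keeps, for every ROI, directed edges
   to the k ROIs with the largest *signed* correlation (self-correlations
   excluded, ties broken toward the lower index). Ranking uses the raw
   coefficient, not its absolute value: the graph is meant to capture the
   strongest positive connectivity, the same quantity thresholding
   approaches act on. The graph is directed and in general asymmetric.
   `build_random_graph()` draws k neighbors per node uniformly — the
   "random GCN" control that carries no connectivity information.
3. **Edge convolution.** Each frame is one graph signal: node i holds the
   scalar BOLD value of ROI i at that frame (or an F-vector after earlier
   layers). One layer computes, per node,

       x_i' = max over out-neighbors j of ReLU(W [x_i ; x_j - x_i] + b),

   the feature-wise maximum over the k neighbor activations. The
   concatenation of the central features with the neighbor difference makes
   the edge function asymmetric: it sees both the node's own activity and
   its local co-activation pattern. The same weights are shared across all
   frames and all subjects, and the graph is fixed for the model's lifetime.
4. **Architecture.** Five such layers are stacked by default
   (`cgcn_config()`), with skip connections concatenating the outputs of
   layers 1..L-1 as the input of layer L, batch normalization of each
   layer's aggregated node features, a node-to-frame reduction, a temporal
   head (mean over frame embeddings, or a single LSTM whose final hidden
   state is used), and a softmax classifier.

Stacking L layers gives every node a receptive field of its L-hop
out-neighborhood (`receptive_field()`), which is how a sparse graph (k of
3–5) still supports whole-network integration.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 5 (3 for the control comparison) | neighbors per ROI; controls graph sparsity. Small k (3–5) performs best; the package exposes 3, 5, 10, 20 style sweeps through `compare_graphs()`. |
| `features_per_layer` | 8, 8, 16, 16, 32 | conv widths; the bundled benchmarks use 4, 4, 8, 8, 16, which is sufficient at the synthetic problem size. |
| `node_pool` | `max` | node-to-frame reduction. See below. |
| `temporal_head` | `average_pool` | deterministic mean over frame embeddings; `recurrent` (LSTM) is available where temporal order matters. |
| `clip_length` | 100 | training clips of 100 consecutive frames. |
| `initial_lr`, `lr_decay_factor`, `lr_patience_epochs`, `min_lr` | 0.01, 0.5, 5, 1e-6 | Adam with stepwise decay: the rate is halved when validation accuracy stalls, floored at 1e-6. |
| `l2_grid` | 0.1, 0.01, 0.001, 1e-4 | the penalty grid swept by `l2_sweep()`; the run with the best validation accuracy wins, ties to the smaller penalty. |

Model parameters are snapshotted only when a new best validation accuracy is
reached, and the snapshot includes the batch-normalization running
statistics — weights and normalization constants must travel together or the
restored model is meaningless.

## Design choices the literature leaves open

**Node-to-frame reduction.** Nothing pins down how per-node features become
one frame embedding. We provide three options. Global max pooling (the
default, and the convention of the point-cloud EdgeConv lineage) is
permutation-invariant and makes occlusion semantics clean: a zeroed-out ROI
that never wins the max is genuinely absent from the readout. Global average
pooling is the config alternative. The third option, `flatten`, concatenates
all node features; it preserves node-localized co-fluctuation patterns and is
what the bundled identification benchmark uses — with global pooling the
20-way fingerprint task does not train at this problem size, while flatten
reaches near-perfect accuracy. Flatten deliberately gives up permutation
invariance (node identity is the information).

**Skip connections.** Implemented as feature concatenation of conv outputs
1..L-1 into the last conv layer's input — concatenation rather than addition
because widths differ.

**Batch normalization.** Each conv block normalizes its aggregated node
features per channel (batch statistics during training, running statistics at
inference). Without it the 5-layer ReLU-plus-max stack multiplies activation
scale layer over layer and training collapses to the uniform classifier; with
it both heads train reliably. Gradient clipping at global norm 5 and a
Xavier-scaled softmax layer serve the same stability goal.

**Recurrent head.** A single standard LSTM (forget-gate bias 1). The
deterministic average-pooling head is used in all bundled benchmarks so that
every reported number is exactly reproducible from its seed.

**Edge MLP depth.** One linear+ReLU unit per conv block by default; deeper
MLPs are available (`edge_mlp_depth`). The depth-1 case uses an algebraic
shortcut — `ReLU(x_i (Wc - Wn) + x_j Wn + b)` computed from two node-level
products — so no edge-sized tensor is ever materialized; the generic path and
the shortcut are cross-checked against brute-force enumeration in the tests.

**Indexing.** ROIs, nodes, and folds are 1-based everywhere, in the R API and
in all emitted files.

## The synthetic cohort

`generate_cohort()` draws each session as T multivariate-normal frames whose
correlation matrix stacks three planted effects on a block (network)
structure:

* a **group** structure: `within_network_corr` (default 0.4) inside each of
  `n_networks` blocks, `between_network_corr` (0.05) elsewhere;
* a **fingerprint**: one random symmetric perturbation per subject
  (`fingerprint_strength`, sd of the added entries), supported on the
  *informative ROIs* — the members of the first two networks — and identical
  across the subject's sessions. This is the statistical skeleton of
  connectome fingerprinting: FC stable within subject, variable between
  subjects;
* a **class effect** (`group_effect`): a fixed shift of the informative
  networks' within-network correlations, opposite in direction for the two
  classes. The effect sits on within-network entries because the k-NN graph's
  edges concentrate inside networks; a purely between-network effect is
  invisible to a convolution whose receptive fields never leave their block;
* optional per-**site** affine gain/offset distortions (removed by the
  per-record z-scoring that precedes both FC computation and model input)
  and optional AR(1) temporal smoothing.

Every perturbed matrix is projected back to a valid correlation matrix by
eigenvalue clipping at 1e-4 and diagonal renormalization; `truth` carries the
exact sampling correlations, the network assignment, and the informative set.

What the generator does *not* emulate: hemodynamics and BOLD spectra, motion
and physiological artifacts, heavy-tailed noise, non-stationarity. Passing
benchmarks on this cohort therefore demonstrates that the implementation
extracts planted covariance structure under the stated protocol — not that it
would reach any particular accuracy on real HCP or ABIDE recordings.

## The reference benchmarks and their problem sizes

All bundled experiments (`identification_benchmark()`,
`graph_comparison_benchmark()`, `occlusion_benchmark()`) run on a cohort of
20 subjects x 2 sessions, 60 ROIs in 4 networks, 600 frames per session
(a realistic scan length; 100-frame training clips then give six clips per
record), with the 5-layer architecture at widths 4, 4, 8, 8, 16, batch size
12, learning rate 0.01, L2 1e-3, and 10–12 epochs. These sizes were chosen
once as the smallest configuration at which the fingerprint task is reliably
learnable; they are deliberately far below the scale of the real datasets the
architecture was designed for.

* **Identification** (`fingerprint_strength` 0.5): graph and weights from
  session 1 only, identification of the 20 subjects from session 2. Typical
  accuracy at 100 test frames is 0.95–1.00 against a 0.05 chance level, and
  accuracy increases with the number of test frames — single-frame input is
  legal and above chance, 30 frames much better, 100 near ceiling.
* **Connectivity vs random graphs** (k = 3): matched training runs differing
  only in the graph. The contrast is evaluated at 30 test frames, the
  few-frame regime where the connectivity prior matters most; at 100 frames
  both variants saturate on this cohort and the comparison is uninformative.
* **Occlusion** (2 classes, `group_effect` 0.15, fingerprints 0.1 as
  nuisance): a max-pooling model is trained on session 1, then every ROI is
  zeroed one at a time (after z-scoring, so "zero" is the ROI's mean) over
  session-2 windows, and the accuracy drop is the ROI's saliency. The group
  effect is sized so the classifier is good but below ceiling: with a much
  stronger effect the within-network class signal is so redundant that no
  single ROI matters and every drop is exactly zero. Session-2 records are
  sliced into six 30-frame windows each (`slice_into_windows()`) to give
  the accuracy a granularity of 1/120 instead of 1/20. Saliency maps from
  the three seeds are averaged before scoring against the planted
  informative set, mirroring how occlusion patterns are averaged across
  cross-validation folds in practice.

## Numerical notes and degenerate inputs

* Correlation requires non-constant columns; constant ROIs are reported by
  index everywhere (`compute_fc`, `zscore_signals`).
* Ties: neighbor ranking breaks correlation ties toward the lower node
  index; argmax prediction ties resolve to the first class; the L2 sweep
  resolves validation ties toward the smaller penalty.
* The max aggregation and ReLU are non-differentiable on measure-zero sets;
  the backward pass uses the standard subgradient (first-argmax routing,
  inactive below zero). Analytic gradients are verified against central
  differences at generic parameter points in the test suite.
* Training aborts with a diagnostic on non-finite loss rather than silently
  continuing.
* Clips shorter than `clip_length` are never fabricated: records shorter
  than one clip are an error, trailing remainders are dropped.
* Test-time records are z-scored over their full length, then cut to the
  requested frame count, so single-frame evaluation is well defined.

## Known limitations

* The graph is static across layers, frames, and subjects by design;
  learned or dynamic graphs are out of scope.
* Evaluation uses the first n frames of a record and a single clip per
  record; multi-clip fusion rules are not implemented.
* The LSTM head is implemented and gradient-checked but not used by the
  bundled benchmarks; at these problem sizes the deterministic mean head is
  equally accurate and exactly reproducible.
* Pure-R training at realistic HCP/ABIDE scale (hundreds of subjects,
  200+ ROIs, 1200 frames) is not practical; the package targets method
  study and desk-scale experimentation.
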