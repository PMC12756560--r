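---
title: "Multimodal toxicity prediction with moltitox: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal toxicity prediction with moltitox: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In vitro toxicity panels such as Tox21 score each compound against 12 binary
endpoints (7 nuclear-receptor and 5 stress-response assays), with most
compound-endpoint pairs unlabeled. A single molecular representation —
topology, chemical language, depiction, or spectroscopy — captures only part
of what drives activity. `moltitox` predicts all 12 endpoints jointly from
four representations of the same molecule and fuses them with self-attention,
so that the model can weight modalities per sample:

* **Graph**: atoms as nodes (78 features each), bonds as directed edge pairs
  with a 4-way bond-type one-hot, encoded by an edge-aware graph isomorphism
  network (GINE).
* **SMILES**: regex-tokenized strings padded/truncated to 202 tokens, encoded
  by a small pre-norm transformer with masked mean pooling.
* **Image**: a deterministic 224 x 224 RGB depiction rendered from 2D
  coordinates, encoded by a residual CNN whose global pooling yields a
  512-dimensional backbone vector under the default configuration.
* **Spectrum**: the carbon-13 NMR peak list discretized into 260 one-ppm bins
  over [-20, 240) ppm, encoded by a 1D CNN with a 768-dimensional backbone
  output.

Each encoder ends in an MLP projection head; the four embeddings are
projected to a common dimension `d_e`, stacked in the fixed order (graph,
smiles, image, spectrum), passed through one shared multi-head
self-attention block `Z = MultiHead(X, X, X)`, mean-pooled, and mapped to 12
endpoint logits.

## The GINE update

Each of the `L` graph layers updates node `v` as

$$h_v^{(k)} = \mathrm{MLP}^{(k)}\!\Big((1+\varepsilon^{(k)})\,h_v^{(k-1)} +
\sum_{u \in N(v)} \mathrm{ReLU}\big(h_u^{(k-1)} + e_{u,v}\big)\Big),$$

followed by batch normalization, ReLU and dropout, with a learnable scalar
$\varepsilon^{(k)}$ initialized at 0. The raw 4-dimensional bond one-hot is
linearly projected to the hidden dimension once and shared by all layers
(the update adds edge features to hidden node states, so their dimensions
must agree; a per-layer projection would only add parameters at this scale).
A linear input projection maps the 78 raw node features into the hidden
dimension so that $h^{(0)}$ lives in the same space. Global sum pooling over
nodes precedes the projection head; sum pooling makes the embedding exactly
invariant to node relabeling and additive over disconnected components, both
of which are verified properties in the test suite.

## Missing spectra and the learnable token

Carbon-13 spectra are available for only part of any realistic compound set
(36% is the default emulated availability). The spectrum encoder is
*trained* only on spectrum-present records; at fusion time, a learnable
**missing token** — a parameter with the dimensionality of the spectrum
embedding, initialized to zeros — is substituted for the spectrum embedding
of every spectrum-absent sample, *before* the shared projection, so the
projection matrix is common to the real and missing paths.

One numerical subtlety is worth recording. The modality projections are
biased linear maps followed by ReLU, and the bias is initialized uniformly
in $\pm 1/\sqrt{d_m}$ rather than at zero. With a zero bias (or no bias at
all), the pre-activation of the missing-token path is exactly zero, the ReLU
subgradient at zero is zero, and the token would receive no gradient, ever.
A nonzero bias keeps about half the ReLU units live from the first step, so
the token trains on any batch that mixes present and absent spectra; on a
batch where every sample has a spectrum its gradient is exactly zero. Both
behaviors are asserted in the tests.

## Fusion block

The attention block is the plain shared multi-head self-attention applied to
the M modality tokens, with the fused vector the arithmetic mean of the M
attended rows. No residual connection or layer norm wraps the block by
default: the fused-equals-mean-of-attended-rows identity (and the
single-token case, where the attention map is exactly [[1]]) holds only for
the plain form. A standard pre-norm residual variant is available behind
`fusion_config(residual = TRUE)`. The head is
Linear(d_e, d_e) + ReLU + dropout, Linear(d_e, d_e/2) + ReLU, Linear(-, 12);
logits stay pre-sigmoid until metrics are computed.

Attention maps are retained per sample (heads x M x M, rows query, columns
key) and summarized per split by averaging over samples and heads.

## Training protocol

Training is two-phase. Phase one trains each encoder independently with a
12-task linear probe under the masked objective (50 epochs maximum, batch
32, early stopping with patience 10 on validation macro ROC-AUC, best epoch
restored). Phase two freezes all encoders — their embeddings are precomputed
constants, so encoder weights are bit-identical afterwards by construction —
and trains only the fusion parameters and the missing token (30 epochs
maximum, patience 5). The objective is binary cross-entropy with logits
averaged over *observed* entries only; a label of -1 or an empty cell means
missing, and masked entries influence neither the loss nor any gradient
(bit-exact, tested). A per-task mean-of-means weighting is available behind
`per_task_loss = TRUE`. The optimizer is Adam at learning rate 1e-3 with no
weight decay by default. Endpoints whose validation fold has a single class
are skipped in the early-stopping metric; if the metric is undefined
outright (possible for tiny spectrum-present subsets), training runs to its
epoch budget and keeps the latest weights.

Hyperparameter search, where wanted, is a seeded uniform random search over
a discrete space (`hyperparameter_search()`); it replaces a model-based
optimizer to keep the tested core dependency-free.

One protocol refinement addresses a failure mode specific to small data.
Best-epoch selection assumes the validation metric can rank epochs; when a
validation fold holds only a few dozen molecules — and for the spectrum
encoder only its spectrum-present subset, often ~20 records — the macro AUC
is so noisy that "best epoch" is close to a random draw, and the restored
model can be a barely trained epoch-1 snapshot. The desk-scale profile
(`benchmark_profile("small")`) therefore trains every phase for a fixed
regularized budget and returns the average of the parameters over the
training tail (`swa_start`, stochastic weight averaging): encoders average
roughly the last two thirds of a 8-20 epoch budget with weight decay 1e-4,
and the fusion averages epochs 20-60 with weight decay 1e-3. Averaging the
optimization tail removes the epoch-to-epoch variance that noisy validation
selection cannot handle and consistently improves scaffold-shifted test
performance for every modality subset. `train_config(select_best = FALSE)`
(fixed budget, final weights) is also available. The default profile keeps
the plain early-stopping protocol (50/30 epochs, patience 10/5).

## Scaffold splitting and evaluation

Molecules are grouped by Bemis-Murcko scaffold (ring systems plus linkers,
side chains pruned; the canonical scaffold SMILES is the group key). Acyclic
molecules share one empty-scaffold group by default (`pool_acyclic =
FALSE` gives each its own). Any group larger than a whole validation/test
fold is routed to train up front — such a group cannot occupy a small fold
without destroying the 8:1:1 ratio. The remaining groups are shuffled with
the split seed and assigned whole: train fills to 80% of molecules, then
validation to 10%, the rest is test — so scaffold sets are exactly disjoint
across partitions.
The deterministic largest-first variant sits behind `size_sorted = TRUE`.
The protocol repeats over five seeds; results are reported as mean ± sd
with paired two-tailed t-tests against the four-modality reference.
Degenerate paired tests follow fixed conventions: identical vectors give
p = 1, a zero-variance nonzero difference gives p = 0 with a warning.

In the ablation benchmark, single-modality rows report the trained encoder
with its own 12-task probe head evaluated directly on test (the spectrum
baseline on spectrum-present records, since the bare encoder has no
missing-modality path); multi-modality rows train the attention fusion over
the frozen encoders. ROC-AUC uses the rank formula, equivalent to the pairwise probability with
half credit for ties, and is undefined (excluded from the macro with a log
entry) when a class is absent — whether the macro average should skip such
endpoints is a protocol choice; skipping-with-log is ours. Threshold
metrics (accuracy, balanced accuracy, Cohen's kappa, MCC, sensitivity,
specificity) use the 0.5 probability threshold.

## The synthetic benchmark

All tests and the acceptance experiments run on a self-contained synthetic
benchmark (`synth_config()` / `build_benchmark()`); nothing is downloaded.

* **Molecules** come from a fragment grammar: ring/chain scaffold templates
  with substitution slots. Three toxicophores — aromatic halide,
  nitroaromatic, carbonyl — are attached at configured rates
  (0.30/0.25/0.35 by default), the remaining slots carry neutral
  decorations; every string must pass `parse_and_validate()` and be unique
  under canonicalization. Attachment is rate-controlled rather than left to
  uniform substituent draws so that every endpoint's driving toxicophore
  has enough prevalence for its signal to be statistically recoverable.
* **Spectra** assign one peak per distinct carbon environment: aromatic
  carbons at base 128 ppm shifted by the attached substituent (C-F 163,
  C-OH 155, C-NO2 148, C-NH2 146, C-C 138, C-Cl 134, C-Br 122, C-I 94),
  ketone/aldehyde carbonyls at 180, acids/esters at 172, sp3 next to a
  heteroatom at 60, plain sp3 at 25 — so each toxicophore leaves a distinct
  signature region, as real 13C shifts do. Equivalent carbons (same class
  and neighbor signature) merge; Gaussian jitter (sd 0.8 ppm by default)
  models measurement spread.
* **Labels** follow a calibrated logistic model on toxicophore indicators:
  endpoints 1-4 are driven by ring halogenation, 5-8 by carbonyl presence
  (the spectrum's clearest signature), 9-12 by nitroaromatics and mixtures.
  Intercepts are root-found so positive rates match Tox21-like imbalance
  (targets 0.10-0.32, kept within [0.05, 0.40]; saturated weights clamp to
  the nearest achievable rate). Labels are flipped with probability 0.05
  (0.02 in the high-signal preset, which also scales weights by 1.6) and
  masked per endpoint at rate 0.15. Spectrum availability is Bernoulli at
  0.36.

What this emulates — and what it does not: planted, modality-distributed
signal with sparse labels and partial spectra, at realistic imbalance. It
does **not** reproduce real structure-activity landscapes, activity cliffs,
assay artifacts, or realistic NMR prediction. Passing the synthetic
experiments shows the pipeline recovers signal it provably contains under
scaffold shift; it does not certify real-Tox21 accuracy, which in the
original setting further depends on large pretrained backbones this package
deliberately trains from scratch at small size.

## Numerical and engineering choices

* All neural components run on a small reverse-mode autodiff engine over
  base-R matrices (BLAS-backed GEMMs); gradients of every primitive are
  validated against central finite differences in the test suite.
* Convolutions use im2col gathers with precomputed index maps; pooling is
  average pooling throughout ("pool" unqualified in the architecture
  notes). The image backbone prefixes a fixed p x p average-pool stem
  (default p = 4) before the first convolution — a cheap fixed downsampling
  that preserves the 3 x 224 x 224 input contract while keeping desk-scale
  training tractable; when augmentation is off, the pooled constant input
  is cached per record.
* The spectrum CNN input carries a second channel holding the normalized
  bin position: stacked convolutions with pooling are otherwise
  translation-invariant, and absolute chemical-shift position is chemically
  meaningful (a carbonyl at 180 ppm must not embed like an sp3 carbon at
  25 ppm).
* GELU uses the standard tanh approximation. Batch norms in a frozen
  backbone run on their stored running statistics.
* The SMILES transformer trims every batch to its longest real sequence and
  uses block-diagonal batched attention with additive -1e9 masks for pads
  and cross-sample pairs; embeddings are therefore exactly invariant to the
  configured pad length.
* Determinism: every stochastic step (initialization, shuffling, dropout,
  augmentation, generator sampling) draws from an explicitly seeded
  Mersenne-Twister stream scoped with `with_seed()`, which restores the
  caller's RNG state. Identical seeds reproduce identical runs on the same
  platform; exact bitwise equality across BLAS implementations is not
  guaranteed.
* Edge indices are 1-based, as is idiomatic in R.

## Problem sizes used by the packaged experiments

The packaged acceptance experiments run at desk scale, chosen as the
smallest sizes at which the studied effects are stable: the
fusion-vs-singles experiment uses 600 molecules over 3 scaffold-split seeds
with the high-signal generator preset and the `benchmark_profile("small")`
model sizes (hidden dimensions 64, two- to three-layer encoders, an
8x-pooled image stem, fusion `d_e` 64 with 4 heads, SWA training
throughout); the capacity check overfits 64 molecules; determinism is
demonstrated on 100 molecules over one seed. The
default configurations (`encoder_config()`, 50/30-epoch schedules) match
the full-scale protocol and remain the package defaults.

## Known limitations

A consequence of the desk-scale regularization worth knowing: with strong
weight decay on the fusion, the learned attention maps shrink toward the
uniform distribution (the fused vector then approaches a plain average of
the value-projected modality tokens), so split-level attention summaries
are close to 1/M per modality. Attention heterogeneity of the kind worth
interpreting emerges with larger data and lighter regularization.

* Encoders are trained from scratch; the package provides
  `load_backbone_weights()` as an integration hook for externally
  pretrained backbones but ships no weights and does not validate against
  the originals.
* The fusion is task-agnostic: one attention pattern serves all 12
  endpoints. Task-conditioned fusion is out of scope.
* The 2D depictions are schematic (colored atom disks, line bonds), not
  publication-grade renderings; they carry the structural signal a CNN
  needs at desk scale.
* Aromaticity, implicit hydrogen counts and hybridization are derived with
  standard valence heuristics via OpenBabel's perception; exotic
  organometallics fall back to the "other" atom class.
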