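---
title: "Consistency-preserving cross-modal hashing on multiple manifolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistency-preserving cross-modal hashing on multiple manifolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmhash)
```

## The problem

Clinical archives hold paired multi-modal neuroimages: each subject
contributes, say, one T1-weighted MRI slice and one PET slice, and both carry
the subject's diagnostic label. Cross-modal retrieval asks: given a query
image in one modality, return the most semantically similar images of the
*other* modality. Hashing makes this fast by mapping every sample to a short
binary code \(h \in \{-1,+1\}^K\) so retrieval reduces to ranking by Hamming
distance (equivalently cosine similarity, since for fixed-length ±1 codes
\(\cos = (K - 2\,\mathrm{Ham})/K\)).

Two failure modes motivate the model implemented here. First, supervised
hashing methods that build their similarity matrix directly from labels
collapse all same-class samples onto one code, destroying within-class
("same-semantics") discriminability. Second, different modalities live on
different sub-manifolds of sample space, so a single global similarity
ignores the continuous geometry. The method addresses both with a
*multi-manifold similarity* over the codes and two consistency constraints.

## Similarity on multiple manifolds

For samples of the **same** modality, similarity is plain cosine similarity
of their codes (the homogeneous block \(S_I\)). For samples of **different**
modalities, a heat kernel is applied to a label-modified distance:

\[
S_H(h_i^m, h_j^n) = e^{-D^2(h_i^m,h_j^n)/\tau},\qquad
D = \begin{cases}
\sqrt{1 - e^{-d}} & \ell_i = \ell_j\\
\sqrt{e^{-d}} & \ell_i \neq \ell_j
\end{cases}
\]

with \(d\) the Euclidean distance between codes and \(\tau > 0\) the heat
kernel constant. Same-label pairs get similarity 1 at \(d = 0\) decaying
towards \(e^{-1/\tau}\); different-label pairs start at \(e^{-1/\tau}\).
These blocks assemble into the symmetric \(MN \times MN\) multi-manifold
similarity \(S_M\) (modality-major order), built by
`multi_manifold_similarity()`.

Note a deliberate fidelity choice: as printed, the different-label branch
*increases* with growing code distance, so minimizing the pairwise loss pulls
different-label pairs toward *smaller* Euclidean distance. This may well be a
branch-convention slip in the published formula, but we implement it
literally; `swap_distance_branches = TRUE` exposes the swapped variant for
experimentation, and it is off by default everywhere. Empirically the model
separates classes anyway, because the dominant repulsive signal for
different-label pairs comes from the indicator term, and this "keep clusters
near each other" pressure is one reason binarized codes retain within-class
variety.

## Losses

* **Multi-semantic consistency** \(J_1\): encoder-stage class predictions
  \(y_i^m\), decoder-stage predictions \(r_i^m\) and one-hot labels
  \(\ell_i\) are tied together by
  \(\sum_{m,i} \|y_i^m-\ell_i\| + \|r_i^m-\ell_i\| + \|y_i^m-r_i^m\|\)
  (Euclidean norms, not squared — gradients keep unit magnitude until the
  predictions match exactly).
* **Multi-manifold similarity preservation** \(J_2\): over all ordered
  modality/sample pairs, \(\log(1+e^{S_M}) - I(\ell_i,\ell_j)\,S_M\). Every
  per-pair term is non-negative. Self-pairs have constant similarity 1 and
  are included exactly as the double sums are written (constant offset, zero
  gradient); `include_self = FALSE` drops them for reporting.
* **Laplacian-embedding reference** (`laplacian_embedding_loss()`):
  \(\sum \frac12 S_{ij}\|H_i - H_j\|^2\) on row-normalized codes. At the
  fixed point of \(\log(1+e^s) = 2s\) — which is \(\ln((1+\sqrt5)/2)\), the
  log golden ratio, exposed as `theorem_fixed_point()` — the pairwise loss
  coincides with this classical graph-embedding objective. The package
  treats this as a numerical probe of the manifold-preserving invariance
  claim, not as a training objective.
* **Quantization penalty**: the printed objective uses
  \(\|h - \mathbf 1\|_1\), the L1 distance to the *all-ones* vector, summed
  over a double modality/sample index that multiplies each code's term by
  \(2MN\). Two aspects deserve care. (a) The all-ones target conflicts with
  the \(\{-1,+1\}^K\) code space: driving every bit toward +1 erases the
  codes. `quantization_regularizer()` therefore also offers the standard
  magnitude form \(\||h| - \mathbf 1\|_1\), and the *training default* is
  the magnitude form, while the loss function's own default remains the
  literal printed form. (b) The \(2MN\) multiplicity is a constant factor
  that only rescales the term against \(\alpha\) and \(\beta\); the
  `count = "once"/"pairwise"` switch exposes both conventions, with
  per-code counting as the default so closed-form values (0 at all-ones,
  \(2K\) at all-minus-ones) hold as stated.

The total objective is \(\alpha J_1 + \beta J_2 + \mathrm{reg}\);
\(\alpha = 0\) and \(\beta = 0\) give the two published ablation variants
(similarity-only and consistency-only).

## Architecture

`mmhash_model()` builds an asymmetric auto-encoder: one **encoder per
modality** (pseudo-Siamese — identical architecture, unshared weights, used
for every \(M \ge 2\) since MRI and PET statistics differ), a **single light
fully-connected decoder** shared across modalities mapping features to
relaxed codes via tanh (so training codes live strictly inside
\((-1,1)\)), and two **semantics-preserving attention branches**: linear
softmax heads on the features (encoder stage) and on the codes (decoder
stage). "Linear MLP" is taken at its word — a single linear layer plus
softmax, since stacked linear layers collapse to one. Binarization is
\(\mathrm{sign}\) with the fixed tie rule \(\mathrm{sign}(0) = +1\).

The desk-scale backbone is a 2-layer MLP on flat inputs (default hidden
width 64, feature dimension 16 with the validated constraint \(D < Z\));
convolutional backbones belong to GPU-scale image experiments and are
rejected with an informative error rather than half-implemented. The encoder
always holds more parameters than the decoder; the test suite asserts this
asymmetry.

Because no neural-network framework is part of this package's dependency
footprint, the forward pass, backpropagation and Adam are written in base R.
Correctness is guarded two ways: analytic gradients of \(J_2\) and the
quantization penalty are checked against central finite differences
(tolerance 1e-4 relative), and full-network stage gradients were verified
the same way during development.

## Three-stage training

`mm_train()` (wrapped by the fitting function `mmhash()`) runs:

1. **Encoder pre-training** — encoder + encoder-stage branch against
   \(\sum\|y-\ell\|\); decoder untouched (bit-identical, asserted in tests).
2. **Decoder pre-training** — decoder + decoder-stage branch against
   \(\sum\|r-\ell\|\) plus the quantization penalty; encoders frozen.
3. **Fine-tuning** — all parameters against the total objective with Adam
   (\(\beta_1 = 0.9\), \(\beta_2 = 0.999\), \(\epsilon = 10^{-8}\)).

Per-stage objectives follow the minimal reading of the published three-step
description; each stage's iteration budget is a separate control parameter.
Batches contain the same subject indices across all modalities (strong
pairing), sampled without replacement per epoch under the control seed, so
fixed seeds give bit-identical histories and parameters on one CPU thread.

Defaults: batch size 20 (as published); desk-scale learning rate \(10^{-3}\)
with 150/100/200 iterations for the three stages — the published initial
rate \(10^{-6}\) at 500 iterations accompanies an AlexNet-scale backbone and
does not move a tiny MLP measurably, so it is kept behind the `"adni2"` /
`"oasis3"` presets (which also set \(\alpha = 0.3, \beta = 1\) and
\(\alpha = 0.1, \beta = 1\) respectively, the values selected on those
datasets). The desk default weights are \(\alpha = 0.3\), \(\beta = 1\),
\(\tau = 1\); \(\tau\) is nowhere stated in the source material and 1.0 is
the neutral heat-kernel choice. Similarities are computed on relaxed codes
during training (differentiability) and on binarized codes at evaluation.

## Synthetic study conditions

`generate_paired_data()` emulates what matters statistically about strongly
paired neuroimaging data and nothing else: class-conditional latent centers
on a low-dimensional patch (intrinsic dimension 4), within-class spread 0.5,
per-modality fixed random smooth maps (linear + sinusoidal bend) into
\(Z = 64\) dimensions, Gaussian noise, balanced classes, and complete
pairing. The desk recipe is \(M = 2\), \(N = 150\), \(C = 3\),
class separation 4 (minimum pairwise distance between latent centers),
noise 0.1, seed 7 — separable enough that retrieval success is the expected
outcome, and small enough to train in seconds on one CPU. The 8/2
subject-level stratified split mirrors the published protocol; 300 subjects
split into exactly 240/60.

What passing on this generator does **not** show: robustness to MRI/PET
intensity distributions, registration error, scanner effects, class
imbalance, or any anatomical structure. The generator is a statistical
stand-in, which is why the package also ingests real single slices from
NIfTI volumes (`extract_slice()`, middle-slice convention, min-max intensity
normalization) for users with data access.

## Evaluation

`cross_modal_eval()` binarizes the test codes and evaluates every ordered
modality pair: mean average precision over *all returned results* (no rank
cutoff; `map_at` exposes cutoffs), precision@k curves, and the mean of the
directional mAPs — the M→P / P→M / Average layout. Relevance is same-class
membership; ties in ranking break by ascending gallery index; queries whose
class is missing from the gallery score 0 with a warning. Vectorized metrics
are tested for exact equality against naive per-query loops, and
label-shuffled codes are checked to sit at the class prior.

On the desk recipe both directional mAPs reach ≥ 0.8 (typically 1.0), and
the binarized test codes within each class are not all identical — the
"same-semantics discriminability" claim at the smallest scale at which it is
literally testable. The code table for that check pools both modalities'
test codes of a class, i.e. all codes carrying that semantic label; with ten
test subjects per class and 16 bits, per-modality-per-class diversity is not
guaranteed at the optimum of the objective (whose similarity terms align
same-class codes), and the pooled reading is the stable, honest one at this
problem size.

## Numerical choices and degenerate inputs

* Zero-norm code rows make cosine undefined; they raise an explicit
  degenerate-input error everywhere rather than emitting NaNs.
* At non-differentiable points (coincident codes, L1 kinks) subgradient 0 is
  used; duplicate codes between distinct samples are legal inputs.
* `sign(0) = +1`, fixed.
* Heat-kernel and cosine entries are clamped to their theoretical ranges
  against floating-point drift; assembled similarity matrices are exactly
  symmetric by construction (transpose assignment, not recomputation).
* File writes are atomic (temp-then-rename), so interrupted runs never leave
  truncated tables.

## Known limitations

* The collapse pressure of the similarity-preserving loss means within-class
  binary-code diversity is a finite-training property, not an equilibrium
  one; very long fine-tuning schedules reduce it.
* The literal quantization form is faithful but self-defeating (see above);
  results quoted here use the magnitude form during training.
* Only the MLP backbone is implemented; 2-D inputs are flattened.
* Multi-label data are rejected: the label model is strictly one-hot.
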