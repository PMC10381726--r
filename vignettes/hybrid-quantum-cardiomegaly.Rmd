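---
title: "Hybrid classical-quantum classification of chest radiographs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid classical-quantum classification of chest radiographs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcxr)
```

# Overview

`qcxr` implements a hybrid classical-quantum transfer-learning pipeline for
binary cardiomegaly detection on frontal chest radiographs. A (frozen or
fine-tuned) convolutional feature extractor feeds one of three trainable
classifier heads:

* **classical (CC)**: linear(f, 512) → ReLU → linear(512, 2);
* **quantum expectation (CQ)**: linear(f, n) → tanh → n-qubit parameterized
  quantum circuit (PQC) → per-qubit Pauli-Z expectations → linear(n, 2);
* **quantum sampling (CQ)**: as above, but the circuit is read out as class
  probabilities over D basis classes (basis index mod D) → linear(D, 2).

The two output logits pass through a softmax; training minimizes the mean
cross-entropy. Softmax over two logits has the same decision surface as the
sigmoid formulation sometimes drawn in high-level diagrams, and pairs
naturally with the cross-entropy loss, so it is the form implemented here.

Everything is exercisable without clinical data through a synthetic
radiograph generator whose class labels are governed by the cardiothoracic
ratio (CTR).

# The quantum circuit

The PQC acts on n qubits initialized in the ground state. The layout is:

1. a Hadamard on every qubit (uniform superposition);
2. an RY(φᵢ) data-encoding rotation per qubit;
3. a trainable RY(θ) layer on all qubits;
4. `depth` blocks, each a linear CNOT entanglement chain (control i →
   target i+1) followed by a trainable RY(θ) layer;
5. a final trainable RY(θ) layer.

The trainable parameter count is therefore **P = n·(depth + 2)**; the
default n = 4, depth = 4 circuit has 24 trainable parameters. A
one-rotation-layer-per-block layout would give 16 or 20 parameters at the
same depth; the pre- and post-rotation layers are the convention
`build_pqc()` pins. Gate set: {H, RY, CNOT} only; no
noise models or density matrices — the simulator is a dense statevector
with qubit 0 as the most significant bit of the basis index (a convention
the tests pin explicitly).

Encoding angles are produced from the classical layer as φ = (π/2)·tanh(u),
a bijection of the tanh range onto (−π/2, π/2); the scale is a package
convention (any fixed scale works; π/2 uses the full nondegenerate RY
range).

The sampling head maps a measured basis index b to class b mod D. Modulo is
the simplest surjective map of 2ⁿ outcomes onto D classes and is what the
package documents and tests; parity-based maps would be an equivalent
alternative. In shots mode the class probabilities are empirical
frequencies of `shots` simulated draws (default 10 for the sampling head,
matching the training protocol; the expectation head always uses exact
expectations).

# Gradients

All RY angles (trainable and encoding alike) admit the exact parameter-shift
rule ∂E/∂a = [E(a + π/2) − E(a − π/2)]/2 for any observable linear in the
density matrix. The package computes full Jacobians of the measurement
layer with respect to θ and φ this way, batching every shifted circuit as
an extra column of one statevector pass, and composes them with the
reverse-mode gradients of the surrounding linear/tanh layers by the chain
rule. Encoding-angle gradients are what lets the loss backpropagate into
the classical layer below the circuit.

In shots mode the gradient is deliberately computed on the exact
expectations: shot noise perturbs the forward pass only. This avoids
2P·shots extra circuit draws per step, and the shot count is a forward-pass
quality knob, not part of the gradient definition.

# Training protocol

`train()` implements the training protocol: Adam (β₁ = 0.9, β₂ = 0.999,
ε = 1e−8), learning rate and L2 weight decay 1e−4 (decay folded into the
gradient), batch size 8, 20 epochs, cross-entropy loss. The **freezer**
option freezes the extractor's (pretrained) parameters for the first 2
epochs — the classifier head always trains — after which the extractor is
released. Epoch losses are means over batches of the mean batch
cross-entropy.

Augmentation is a reduced random-augmentation policy: 2 ops per image per
epoch from {rotate ±15°, translate ≤10%, brightness ±20%, contrast ±20%,
autocontrast}, then autocontrast with probability 0.5, training split only,
re-drawn each epoch. A full 14-op random-augmentation policy is out of
scope; the magnitudes above are fixed package defaults. Batch order and augmentation draws come from an epoch-derived
seed, so e.g. classical and quantum runs under the same seed see identical
batch orders and augmentations — the equal-footing comparison the protocol
requires.

Splits are stratified (the curated cohort is balanced by construction;
stratification preserves that in folds): one 70/30 holdout or k = 10 folds
whose test sets partition the data.

# Evaluation and statistics

`compute_metrics()` reports AUC (Mann-Whitney rank form, ties credited
0.5), accuracy, balanced accuracy, and per-class precision/recall, with
undefined precisions flagged `NA` rather than coerced to 0. The decision
threshold is 0.5 on the class-1 probability, the symmetric choice for a
balanced design. Fold summaries use t-based 95% CIs
(mean ± t₀.₉₇₅,ₖ₋₁·s/√k) — with k = 10 the normal approximation would be
anticonservative. Model comparisons: paired t over folds, Pearson 2×2
chi-square without continuity correction (the star levels of the cohort
table are reproduced without it at these sample sizes), and a Welch t
computed from printed summary statistics.

# Effective dimension

For the quantum layer viewed as p(y|x; θ) (class readout of the circuit),
the empirical Fisher information is the class-weighted average of score
outer products, with scores from parameter-shift gradients. Matrices are
normalized so the mean trace equals P, and the normalized global effective
dimension is

d_eff(n) = 2·log E_θ √det(I + c_n F̂(θ)) / log c_n,  c_n = γn/(2π log n),

reported as NGED = d_eff/P. Defaults: γ = 1 (the customary scale),
30 θ-samples uniform on [0, 2π)^P, 30 encoding samples uniform on
(−π/2, π/2)ⁿ (the image of the tanh encoding layer). √det is evaluated via
eigenvalue log-sums (Σ log1p(c·λ)) so the curve is finite far beyond
n = 10⁶. "Global" means averaged over the θ prior, not evaluated at a
trained point. Probabilities below 1e−12 are clamped (and counted) before
taking logs. Absolute NGED values depend on the sampling configuration, so
the package checks the qualitative ordering — the D = 4 readout has higher
NGED than D = 2 over a wide range of n — on ≥ 80% of a log-spaced grid.

# Saliency

`gradcam_pp()` computes Grad-CAM++ over the toy extractor's post-ReLU
convolutional maps. The pixel-wise weights are
α = ∂² / (2∂² + Σ A·∂³) with w_k = Σ α·max(0, ∂Y/∂A); derivatives are taken
on the pre-softmax class score passed through the exponential, the standard
Grad-CAM++ construction. For a locally linear score (the ReLU head) the
higher derivatives vanish and α collapses to g²/(2g² + ΣA·g³) — exactly the
published fallback, and the form the analytic unit test checks. Because the
score reaches the maps only through global average pooling, all derivatives
are constant within a map, so α is computed per map in closed form from the
per-feature derivatives of the head: first derivatives analytically,
second/third by five-point stencils on the smooth quantum heads (exactly
zero for the piecewise-linear classical head, where stencils across ReLU
kinks would be meaningless). Heads with a shot-sampled circuit are
differentiated through the exact-expectation path. The map is upsampled
bilinearly into original-image coordinates (zero outside the center crop)
and max-normalized.

`classify_trustworthy()` operationalizes a reader's review criteria with
four exposed thresholds (all 0.5 by default): hot zone = components above
half the maximum; verdicts in order — not visible, extensive (> half the
image), multiple zones (second component ≥ half the largest), outside the
cardiac area (largest component covers < half the heart), else trustworthy.
Trustworthiness rates in clinical reader studies come from blinded human
review; these rules are an automated operationalization, comparable in
spirit, not in value — "most of the cardiac silhouette" and "similar
size" have no canonical quantification, so the defaults are declared, not
inferred.

# Synthetic data

`generate_cxr()` draws a dark background, a bright thorax ellipse with two
darker lung fields, and a bright cardiac ellipse low-central in the thorax
whose maximal width is ctr × the inner thoracic width (heart height fixed
at 0.8 of its width, so mask area scales as ctr²). Control CTRs are
uniform on [0.35, 0.45] and cardiomegaly on [0.55, 0.70] — the curation
thresholds (≤ 0.45 / ≥ 0.55) with a deliberate gap, making the classes
separable by construction so training checks are stable; `hard_mode`
narrows the ranges to [0.42, 0.49] vs [0.51, 0.58] for stress testing.
Real cohorts have no such gap. Pixel noise is Gaussian (sd 0.03), placement
jitter is ±0.5% of the image size, and an effusion-like basal opacity
confounder appears with probability 0.15 independently of class.
Demographics mirror the shape of a curated cohort description (control age
~ N(54.4, 17.2), disease ~ N(62.9, 17.1), truncated to [18, 100]; male
fractions 0.65 vs 0.59) so the summary-statistics operations have
realistic fixtures.

What the generator does **not** emulate: anatomy beyond ellipses, ribs,
projection physics, device markers, co-occurring findings, label noise
correlated with difficulty, and the continuum of borderline CTRs. Passing
tests on synthetic data therefore demonstrate that the pipeline's machinery
(optimization, gradients, metrics, saliency geometry) works — not clinical
performance.

`measure_ctr()` is the widest-row ratio of the two masks; generated records
round-trip their target CTR within 0.02 (pixel quantization).
`requalify_labels()` applies the curation rule to a manifest CTR column
(flip positives with CTR ≤ 0.45 to control, negatives with CTR ≥ 0.55 to
cardiomegaly, leave intermediate labels intact); it is idempotent.

# Numerical and design notes

* Statevector norm is preserved to 1e−9 through arbitrary gate sequences;
  circuit output is tested against an explicit 2ⁿ×2ⁿ kronecker-product
  oracle to 1e−10 (n ≤ 4).
* Parameter-shift gradients are exact; tests compare against central
  finite differences at 1e−6 over 100 random cases.
* Weight initialization: uniform ±1/√fan_in for linear layers, θ uniform on
  [0, 2π), all under one seed, so whole training runs are bit-reproducible
  (exact measurement mode).
* Uncertain (−1) manifest labels: the mining policy of the source cohort is
  unpublished, so the handling is an explicit config policy
  ({exclude, as_negative, as_positive}, default exclude); blanks are
  treated as negative during curation.
* The toy extractor (f = 64 random 5×5 filters over a 28×28 block-pooled
  grid, ReLU, global average pooling) is the differentiable stand-in for a
  pretrained CNN; `external_extractor()` accepts any adapter producing
  f-vectors (e.g. f = 1024/4096) but none is required or bundled.
* Problem sizes used by the package's own acceptance checks: 300 images
  per class at 320 px, f = 64, 20 epochs — large enough for both heads to
  reach test AUC ≥ 0.95 under the protocol above, small enough for a
  single CPU. The effective-dimension check uses the default 30×30
  samples on a 9-point log grid n ∈ [10², 10⁶].

# Known limitations

* The classical head's effective dimension is not computed: P = 512·f + …
  makes the Fisher matrix impractically large, so the analysis is
  restricted to the quantum layer.
* Only {H, RY, CNOT}; no hardware backends or noise simulation.
* Grad-CAM++ is the only saliency method; trustworthiness verdicts are
  rule-based, not human.
* The synthetic generator's separability gap makes headline clinical
  metrics (AUC ≈ 0.93 on real cohorts) meaningless to compare; no attempt
  is made to reproduce them.
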