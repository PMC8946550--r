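---
title: "Denoising and classifying lens-free shadow images: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising and classifying lens-free shadow images: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement this package emulates

In lens-free shadow imaging (inline holographic) cytometry, a semi-coherent
source — here a pinhole-conjugated LED with a 470 nm peak — illuminates cells
held in a disposable chamber a few hundred micrometers above a bare CMOS
sensor. Each micro-object casts a characteristic diffraction ("shadow")
pattern of concentric rings whose geometry and contrast depend on the
object's size and optical properties, so a single sensor frame captures
hundreds of classifiable single-cell signatures without any lens.

Real micrographs of this kind are not freely available, so `shadowcyto`
ships a first-class synthetic generator and treats it as the data source for
every quantitative claim the package tests about itself.

## Forward optical model

The simulator represents a particle as a circular amplitude/phase object: a
disk of diameter $d$ that attenuates the field amplitude by an opacity
$\alpha$ and retards its phase by $\phi$, with a 1-pixel anti-aliased edge.
The field at the sensor is computed by angular-spectrum propagation: the
transmission is decomposed into plane waves with a 2-D FFT, each component
multiplied by $\exp\!\big(i 2\pi z \sqrt{1/\lambda^2 - f_x^2 - f_y^2}\big)$,
and evanescent components ($f_x^2+f_y^2 > 1/\lambda^2$) set to zero. At the
default pixel pitch of 2.2 µm the sampling band lies entirely inside the
propagating region, so propagation conserves energy exactly (Parseval), a
property the test suite asserts to 1e-6. $z = 0$ is special-cased to the
identity.

Detection is intensity only, $|u|^2$. Partial spatial coherence of the LED
is emulated by a Gaussian blur of the intensity (default $\sigma$ = 1 px);
this is a deliberate phenomenological shortcut — a full mutual-coherence
treatment is out of scope — chosen because it reproduces the soft-ring look
of measured patterns. The background (unit plane wave) is mapped to 60 % of
full scale before quantization to 8 bits, leaving headroom for bright rings
above the dark central shadow.

Six particle classes are parameterized: RBC (7 µm, opacity 0.6, phase 1.0),
WBC (10 µm, 0.5, 1.5), MCF7 (18 µm, 0.5, 2.0), HepG2 (16 µm, 0.7, 1.2), and
10/20 µm calibration beads (0.9 opacity, 0.5 phase). These constants are
package choices, not measured optical properties: the pixel pitch, the exact
sample-to-sensor distance (default 300 µm of "a few hundred") and the cell
optics are not published for the reference instrument. Each rendered
particle jitters diameter, opacity and phase by ±10 % uniformly and shifts
the center sub-pixel, so crops within a class vary the way cells in a
chamber do. What the generator does **not** emulate: sensor shot/read
noise, non-uniform illumination, overlapping or touching cells, debris, and
intra-class morphological heterogeneity beyond the parameter jitter.
Consequences are discussed under *Limitations*.

A whole synthetic frame multiplies the (non-overlapping) particle
transmissions into one field and propagates it coherently in a single step;
placement is rejection sampling with a minimum pairwise separation (default
40 px) and an edge margin wide enough for the rotation context of every
crop.

## Dataset protocol

Single-particle crops use a 66×66 px window, large enough for the full ring
system plus minimal background. Augmentation rotates each base crop
clockwise in 10° steps, giving 36 orientations; with 55 base crops per class
this yields 1980 crops per class and 11 880 over six classes. Each rotation
is resampled with bilinear interpolation from a 94×94 context window
(⌈66·√2⌉, rounded to matching parity) around the particle center, so no
corner pixel of a rotated crop is undefined. Interpolation maps are cached
per (size, angle), making augmentation deterministic and cheap.

Because rotated copies are near-duplicates, fold assignment works on whole
(class, base crop) groups. Two modes exist:

* **group-aware** (default): every fold holds whole 36-rotation groups —
  no leakage anywhere;
* **paper-compatible**: per class 1490/166/324 train/validation/test, where
  the 324-crop test fold is exactly 9 whole groups but the train/validation
  boundary may cut within a group. The published split sizes cannot be
  fully group-aligned (1490 and 166 are not multiples of 36); this mode
  confines the compromise to the train/validation boundary, where it cannot
  bias test estimates.

Noise injection is additive zero-mean Gaussian on the raw 8-bit intensity
scale (variance 100 ⇒ σ = 10 gray levels), variances 100–600, clipped to
[0, 255]. Noisy/clean pairs are drawn once per dataset from a seed, not
resampled per epoch, so training runs are exactly reproducible.

## Denoising autoencoders

All learned denoisers consume pixels scaled to [0, 1] and are trained with
Adam on mean squared error; outputs are rescaled and clipped to the 8-bit
range.

**ELM.** The extreme-learning-machine autoencoder is a single hidden layer
of 2000 sigmoid units with input weights drawn uniformly on [−1, 1] (biases
on [0, 1]) and never trained. With hidden activations $H$ and clean targets
$T$, the output weights solve the ridge system
$\beta = (H^\top H + I/C)^{-1} H^\top T$ (default $C = 10^3$). The retained
inverse term $P$ supports the online-sequential update
$$P_{k+1} = P_k - P_k H^\top (I + H P_k H^\top)^{-1} H P_k,\qquad
\beta_{k+1} = \beta_k + P_{k+1} H^\top (T - H\beta_k),$$
which reproduces the batch solution on the union of all batches to
numerical precision — the property that makes the model incrementally
extensible. The test suite asserts batch-vs-oracle agreement to 1e-8 and
sequential-vs-batch to 1e-6 over several partitions.

**CNN.** The convolutional autoencoder is the kernel cascade 3, 3, 5, 5, 7,
7, 1 with 32 filters per layer (one filter in the final 1×1 condensing
layer), ReLU activations, and same padding throughout, so any crop size
passes through unchanged. Two fully connected reference autoencoders
(512-256-512 and 256-128-64-128-256 hidden units, ReLU) flatten the crop
instead.

**Initialization choice.** Conv autoencoders are built with a
*pass-through* initialization: He-scaled noise (shrunk fourfold) plus a unit
center tap on the first filter of every layer, so the freshly built network
starts close to the identity map. Training then starts near the noise floor
and spends its budget learning the denoising correction rather than
relearning reconstruction; on this problem it reaches in a few hundred
Adam steps a loss that plain He initialization does not reach in thousands.
This changes only the starting point of optimization, not the architecture.

**Training sizes.** The packaged study trains one denoiser across all noise
variances (100–600 mixed uniformly) on 240 pairs (40 base crops per class at
50×50), batch size 4, learning rate 1e-3 decaying ×0.93 per epoch for 12
epochs. 50×50 is used as the working crop size for the comparison study and
the benchmark evaluates 18 held-out crops (3 per class) at each of the six
variances. These sizes are the package's chosen desk-scale study
conditions; the API accepts arbitrary sizes and budgets, including
per-variance training.

## Classical baselines

The benchmark compares against Gaussian blur (σ = 1), 3×3 box average, 3×3
median, a 5×5 bilateral filter (σ_color = σ_space = 75; deliberately the
common default — the published comparison suggests strong parameter
sensitivity for this filter and no settings are given), and a single-stage
collaborative filter in the BM3D style written for this package: 8×8 block
matching in a ±16 px window, 2-D DCT plus 1-D Haar group transform, hard
thresholding at 2.7σ, and inverse-transform aggregation weighted by retained
coefficients. The BM3D-style baseline receives the true noise σ of each
benchmark condition — an oracle advantage the learned models do not get.
Gaussian and median filtering go through EBImage; the bilateral and
collaborative filters are local implementations (neither exists in the
installed image stack).

## The SNR improvement metric

Denoising quality on a crop is
$$SNR_{imp} = SNR_{out} - SNR_{in},\qquad
SNR_{out} = 10\log_{10}\frac{\sum_i x_i^2}{\sum_i(\hat x_i - x_i)^2},\quad
SNR_{in} = 10\log_{10}\frac{\sum_i x_i^2}{\sum_i(\tilde x_i - x_i)^2},$$
with $x$ clean, $\tilde x$ noisy, $\hat x$ denoised, and sums over all
pixels of the crop ($N$ is the crop area; denoising operates per crop, so
the per-crop reading of $N$ is used). The metric is invariant to a common
rescaling of all three signals, so the choice of evaluation scale (raw
8-bit here, recorded in the benchmark table's `scale` attribute) does not
affect it. Identity denoising gives exactly 0; perfect reconstruction is
reported as the `Inf` sentinel rather than capped; an all-zero clean crop
is an error, not a zero.

## Classifier family

The deep model follows the published layer list exactly: conv 512·3×3 →
maxpool 3×3 → conv 128·3×3 (dropout 0.5) → maxpool 2×2 → conv 64·3×3
(dropout 0.2) → maxpool 2×2 → conv 32·3×3 (dropout 0.2) → maxpool 3×3 →
conv 16·3×3 → maxpool 3×3 → conv 8·3×3 → maxpool 3×3 → FC 256 → FC 128
(dropout 0.2) → softmax. The *intermediate* model is defined here as the
deep model minus its leading 512-kernel block and one pooling stage (kernel
counts 128-64-32-16): the reference description of the intermediate and
fine-tuned variants exists only in a figure, so this is an interpretation,
exposed through the plan API so any variant can be expressed. The *shallow*
member (conv 32·3×3 → pool 3 → conv 16·3×3 → pool 2 → FC 64 → softmax) is
this package's light configuration, and is what the packaged desk-scale
study trains. Max-pooling uses non-overlapping windows (stride = kernel);
a pooling stage that would shrink a small input below one pixel is skipped
with a notice, so one family serves all supported sizes (66–36). Training
uses Adam with categorical cross-entropy.

The packaged classifier study uses 8 base crops per class (36 rotations
each; group-aware 5/1/2 split), input sizes 40–66, 6 epochs at batch 32 —
again a desk-scale choice, not a claim about optimal budgets.

## Transfer learning

To adopt a newly introduced class, all layers are frozen except the final
dense (pre-softmax) layer, which gains one freshly initialized output
column and is retrained on a mix of new-class crops (50 % by default) and
uniformly sampled old-class crops. Freezing is structural — only the last
layer's arrays are ever updated — so backbone weights are bit-identical
afterwards, which the tests assert. Before transfer, the held-out class
cannot be predicted at all (its output does not exist), giving the expected
0 % pre-transfer accuracy; after retraining the class is recognized while
old-class accuracies move by less than a few points. The packaged study
retrains for 40 epochs at learning rate 3e-3: a single softmax layer on
frozen features is a convex-like problem, but it must be run to
convergence — stopping early leaves the boundary between the new class and
its nearest old neighbor (RBC vs. WBC here) miscalibrated, which shows up
as apparent forgetting of the old neighbor.

## Evaluation metrics

Per-class performance uses one-vs-rest confusion counts; accuracy,
precision (= PPV), recall (= sensitivity), specificity, F1 and NPV follow
the standard formulas, are exported rounded half-even to 4 decimals, and a
zero-denominator metric is reported as `NA`/null rather than 0. The test
suite reproduces every derived cell of the published per-class table from
its printed counts. ROC curves sweep all score thresholds with trapezoidal
AUC (equal to pairwise concordance, hence invariant under monotone score
transforms); the implementation is cross-checked against pROC. Count
comparisons report per-class absolute and percent differences between
predicted and reference counts, with simulator ground truth standing in for
the manual reference on synthetic frames.

## Numerical choices and degenerate inputs

* Coordinates are row-major and 0-based with pixel centers on integer
  coordinates; crop centers sit at index ⌊size/2⌋.
* Quantization rounds half-even to the bit-depth range; rotation and
  denoiser outputs are clipped before re-quantization.
* Max-pooling ties resolve to the first maximum in column-major scan order,
  deterministically.
* The ELM falls back to a Moore–Penrose pseudoinverse (with a message) if
  the regularized normal matrix is singular.
* Empty update batches, empty scenes, empty center lists and
  single-group splits are all defined no-op/degenerate cases, not errors;
  impossible placements and incompatible group splits fail with messages
  naming the achievable alternative.
* All randomness flows from user-supplied integer seeds through localized
  RNG scopes that restore the caller's RNG state.

## Limitations

The synthetic benchmark is smoother and more homogeneous than real lens-free
micrographs: patterns are radially symmetric up to jitter, the background is
flat, and class differences are fully parameterized. Classification
accuracies near 100 % on this data therefore demonstrate that the pipeline
learns and preserves the class-distinctive ring structure, not that the
architecture would reach the same numbers on real cells — the published
real-data figures (e.g. ~90 % for the cancer lines) are not reproducible
targets without the original data. Equally, classical filters profit from
the smoothness: the collaborative (BM3D-style) baseline is near its ideal
conditions here, making the learned-vs-classical comparison conservative.
The forward model is scalar and fully coherent save for the Gaussian
coherence surrogate, and no sensor noise model beyond the benchmark's
additive Gaussian corruption is included.
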