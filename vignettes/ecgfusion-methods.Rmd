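---
title: "Methods: the ecgfusion arrhythmia pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ecgfusion arrhythmia pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecgfusion)
```

This vignette is the package's account of its models and of the design
choices that were genuinely open: what each stage assumes, which
parameters matter, what the synthetic generator does and does not
emulate, and the numerical decisions (tolerances, stopping rules,
tie-breaks, degenerate inputs) that the reference descriptions leave
unstated.

## 1. The denoising model

### ICEEMDAN

Empirical mode decomposition (EMD) peels a signal into intrinsic mode
functions (IMFs) by repeatedly subtracting the mean of the cubic-spline
envelopes through the local extrema. Plain EMD suffers mode mixing;
ICEEMDAN suppresses it by ensemble-averaging the *local mean* over
white-noise-perturbed copies. Stage $k$ computes

$$r_k(t) = \frac{1}{I}\sum_{i=1}^{I} M\!\left(r_{k-1}(t) + \alpha\,E_k(\delta_i)(t)\right),
\qquad \mathrm{IMF}_k = r_{k-1} - r_k,$$

where $E_k(\delta_i)$ is the $k$-th EMD mode of the $i$-th white-noise
realization and $M(\cdot)$ the local-mean operator ($M(y) = y$ minus the
first sifted mode of $y$). Because every mode is a difference of
consecutive residuals, the reconstruction $\sum_k \mathrm{IMF}_k + r_K$
is an exact telescoping identity — the package asserts it to $10^{-8}$
relative error on every decomposition, and it holds to machine precision.

**EMD internals** (unstated in most method descriptions, so fixed here
once): natural cubic-spline envelopes through strict local extrema, with
two extrema mirrored about each end point to control end swings; sifting
stops when the normalized squared change between passes drops below
`sift_stop_sd = 0.2` *and* the candidate satisfies the IMF count
property (|#extrema − #zero crossings| ≤ 1), with a 30-pass cap — the SD
criterion alone leaves count violations on structured signals, while
over-sifting past the joint criterion bleeds amplitude information.

**Noise schedule**: the perturbation amplitude is
`noise_std_ratio` × sd(signal) (default ratio 0.2), held constant across
stages, with `ensemble_size = 50` by default; per-realization seeds
derive from the master seed, so the decomposition is bit-reproducible.
A constant schedule (rather than one proportional to the shrinking
residual) keeps each stage's perturbation comparable to the signal;
its side effect is that once the residual is reduced to the trend, the
averaged local means stop changing and the "modes" extracted thereafter
are numerically zero. The stage loop therefore stops when the extracted
mode's energy falls below $10^{-12}$ of the input energy (or when the
residual has fewer than 3 extrema, whichever comes first). On a
3000-sample synthetic ECG with broadband noise this yields 8–9 modes plus
a residual, in line with the order-of-ten modes expected for signals
whose content spans roughly three frequency decades.

### Frequency routing and the 1.5 Hz rule

Each mode's dominant frequency is the FFT magnitude peak (DC excluded),
and the modes are routed into three bands:

* **high-frequency** modes (dominant frequency ≥ `wavelet_split_hz`,
  default 20 Hz), where broadband noise dominates ECG content, are
  wavelet-thresholded;
* **mid-band** modes (1.5–20 Hz) carry the diagnostic ECG content
  (QRS complexes, P and T waves) and pass through untouched —
  thresholding them measurably destroys clean signal, because the
  MAD-based noise estimate reads signal, not noise, in those bands;
* the **low-frequency** content below 1.5 Hz — baseline wander from
  respiration and electrode motion — is cleaned by the 1.5 Hz
  threshold: the sub-cut spectral content of the reconstruction is
  removed with a sharp FFT high-pass. Cleaning the *content* rather
  than discarding whole modes matters: empirical decompositions
  routinely place substantial genuine beat energy (the rhythm
  fundamental sits at 1–1.7 Hz for normal heart rates) into modes
  whose FFT peak lands just below the cut, and discarding such a mode
  costs 10–20% of the signal. Because the high-pass is linear,
  applying it to the reconstruction is exactly equivalent to cleaning
  every component individually.

On clean band-limited input this routing is near-identity (NCC
0.99997 in the suite); on noisy input at 5 dB it removes the baseline
almost completely (error reduction ≈ 90×) and improves SNR by ≈ 9–13 dB
across 20 seeded trials.

### The improved wavelet threshold

Detail coefficients are shrunk with

$$f(x) = \mathrm{sign}(x)\left(|x| - \frac{2T}{e^{(|x|-T)/T} + 1}\right)
\quad (|x| \ge T), \qquad f(x) = 0 \ (|x| < T).$$

The defining limits pin the form down: $f(\pm T) = 0$ (continuity), the
difference from the soft threshold $\mathrm{sign}(x)(|x|-T)$ vanishes as
$|x| \to T^{+}$, and $f(x)/x \to 1$ as $|x| \to \infty$ (hard-threshold
asymptote). The function is odd and never amplifies. $T = 0$ degenerates
to the identity and is allowed.

The transform is a 5-level sym8 pyramid. Boundary handling is
**periodized** rather than symmetric-padded: periodization keeps the
transform square and exactly orthogonal, so perfect reconstruction holds
to machine precision and the thresholding analysis applies coefficient by
coefficient; signals whose length is not divisible by $2^5$ are
zero-padded for the transform and trimmed afterwards. The threshold is
the per-level universal threshold
$T_j = \hat\sigma_j\sqrt{2\ln n}$, $\hat\sigma_j = \mathrm{median}(|d_j|)/0.6745$,
the standard companion of threshold-function work; the approximation band
is never touched.

## 2. Slicing, labeling, partitioning

Windows are 5 s (1800 points at 360 Hz), half-open `[start, start+1800)`
on 0-based sample indices, with stride `window × (1 − overlap_fraction)`;
the overlap fraction defaults to 0.5 (only the existence of overlap is
prescribed; 0.5 doubles the sample count without near-duplicate
adjacent windows). A trailing partial window is dropped. Slice labels
follow four rules — all-N → N; exactly one abnormal type → that type;
several → most frequent; tie → first-occurring — which makes labeling
permutation-invariant except exactly in the tie case, a property the
suite tests both ways.

Partitioning holds out 20% (stratified by label) *before* balancing, so
no held-out segment can serve as a SMOTE neighbor (the suite checks the
intersection is empty); the balanced remainder splits 30/70 into
validation and training, with a fractional sample rounding toward
validation — with the published class sizes (9403, 5935, 5036, 4927,
2655) this reproduces 47,015 balanced samples, 14,105 validation and
32,910 training.

## 3. SMOTE

Canonical SMOTE: each minority class is filled to the majority count by
$x_{new} = x_i + u\,(x_{nn} - x_i)$ with $u \sim U(0,1)$ and $x_{nn}$ one
of the $k = 5$ nearest same-class neighbors under the Euclidean metric on
the raw 1800-vectors. Originals are kept bit-identical and synthetic rows
carry a provenance flag so evaluation can exclude them. Neighbor search
is exact, computed blockwise via the Gram-matrix identity to bound
memory. Balancing operates on the 1-D segments *before* image encoding
(images are then derived per segment), matching the pipeline order in
which encoding is the last step before the network.

## 4. Image encoding

All three encodings operate on the slice after piecewise aggregate
approximation (PAA) to 100 points — each output value the mean of an
18-sample frame — so the matrices are natively 100×100 (`compression =
"resize"` instead encodes at full length and bilinearly resizes; it is
slower and nearly indistinguishable downstream).

* **GADF**: rescale to $[-1,1]$, $\phi_i = \arccos \tilde x_i$,
  $G_{ij} = \sin(\phi_i - \phi_j)$. Antisymmetric, zero diagonal. A
  constant slice has no defined rescaling and errors.
* **MTF**: quantile-bin into $Q = 8$ states (duplicate quantile breaks —
  few distinct values — merge bins; a state with no outgoing transitions
  gets a uniform row), fit the adjacent-pair Markov chain, and set
  $M_{ij} = W_{s_i s_j}$. Rows of $W$ are stochastic by construction.
* **RP**: $R_{ij} = 1$ iff $\lVert x_i - x_j\rVert \le \varepsilon$, with
  delay embedding available but defaulting to none ($m = 1$, $\tau = 1$).
  The threshold $\varepsilon = 30$ is in raw signal units, which is
  meaningful for ADC-scale amplitudes; since the generator and denoiser
  work in millivolt-scale physical units, the pipeline multiplies
  segments by the ADC gain (200 units/mV) before encoding. The stated
  normalization of the embedded series and the raw-unit threshold cannot
  both hold at once; the package resolves this by defaulting to raw
  amplitudes (so ε = 30 keeps its meaning) and exposing `normalize` for
  the other reading.
* **Stacking**: GADF → R via $[-1,1] \to [0,255]$, MTF → G via
  $[0,1] \to [0,255]$, RP → B via $\{0,1\} \to \{0,255\}$, rounding
  half-up (R's banker's rounding would map 127.5 to 128 only half the
  time).

## 5. The dual-channel network

The layer geometry is fixed by the design table and audited cell by cell
in the test suite (`audit_shapes()`): 1-D branch
1×1800 → stem conv(64, k7, s2) → BN → ReLU → maxpool(3, s2) → ICBAM
residual stages (32, 450), (64, 225), (128, 113), (256, 57) → global
average pool → 256; 2-D branch 100×100×3 → conv(64, 7×7) → pool(3, s3) →
conv(32, 5×5) → pool(3, s3) → conv(16, 3×3) → adaptive max pool 3×3 →
144; concatenation to 400 → dropout → dense 200 (ReLU) → softmax over 5.

**ICBAM.** Channel attention pools each channel by mean and max, sums
the two, passes the C-vector through a bottleneck MLP (C → C/r → C) and a
sigmoid, scales the feature map and re-adds it:
$F_1 = F\,W_c + F$. Spatial attention max- and mean-pools across
channels, concatenates the two 1×L maps, convolves (kernel 7, padding 3),
applies a sigmoid and multiplies into $F_1$, then re-adds the *block
input* (global-feature reuse): $F_2 = F_1\,\sigma(\mathrm{conv}) + F$.
With both sigmoids bypassed (weights forced to 1) the module collapses to
$3F$ independent of every attention parameter — the suite uses this as a
regression test that attention is a strict generalization of the plain
residual path. Open choices fixed here: reduction ratio r = 4 (the stage
widths 32–256 make 16 too aggressive); spatial kernel 7; the sigmoid and
the residual re-add are included in the spatial stage (the prose form of
the attention includes them even where the compact formula omits them);
attention channel order is max, then mean.

**Residual blocks** are conv(3, stride, pad 1) → BN → ReLU → ICBAM →
conv(3, 1, pad 1) → BN → add shortcut → ReLU, with a 1×1 projection
shortcut when shape changes; stage 1 narrows 64 → 32 at stride 1 through
its first convolution. The residual-closing BN scale initializes at zero
so a freshly initialized block is its shortcut; other weights are
Kaiming-normal, biases zero, all seeded. The 2-D branch has no listed
normalization; it uses ReLU after each convolution and no BN.

**Implementation.** No deep-learning framework exists in the target
environment, so forward and backward passes are implemented in the
package: convolutions as one BLAS GEMM over an im2col patch matrix built
in C++ (1-D convolutions are the kh = 1 case of the same kernel), with
persistent workspace buffers outside R's garbage-collected heap — GC
tracing of ~300 MB per-step temporaries otherwise dominates runtime —
and manual backpropagation for every layer. Correctness rests on a
finite-difference gradient check that walks every parameter tensor of a
scaled-down network exercising each layer type (relative error < 10⁻³ at
h = 10⁻⁵, loose enough for conditioning, tight enough to catch any
structural error).

**Training** is Adam (β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸) at the reference
recipe — learning rate 0.0007, batch 256, 200 epochs, cross-entropy, no
schedule or weight decay — deterministic given the seed up to
floating-point reduction order. The checkpoint rule is unstated in the
reference description; the package keeps the parameters from the epoch
with the best validation overall accuracy (`keep_best_val`, on by
default), and exposes `stop_loss` as an optional early stop on training
loss. Per-class "accuracy" in the evaluation report is the one-vs-rest
$(TP+TN)/(TP+TN+FP+FN)$; note that published per-class accuracy columns
in this line of work often coincide with sensitivity — the report
computes both explicitly so the two cannot be conflated.

## 6. The synthetic generator: what it does and does not emulate

Records are rendered at 360 Hz as sums of Gaussian bumps per beat
(P/Q/R/S/T-like), with class-specific widths, amplitudes and prematurity:
S narrow and premature with reduced P; V wide, large, inverted T, absent
P; F intermediate; Q low-amplitude and diffuse. Beats sit on a regular
RR grid (default 72 bpm) with i.i.d. class draws from `class_mix`; the
R-peak sample index is exact, so annotations are noiseless. The rendered
record is band-limited above 1.5 Hz (a sharp FFT high-pass at render
time), emulating an AC-coupled, baseline-corrected acquisition front
end: raw Gaussian-bump beat trains would otherwise carry 10–20% of their
energy below 1.5 Hz, a regime real acquisition filtering does not
produce, and one in which no implementation of the 1.5 Hz baseline rule
could be near-identity. The sub-1.5 Hz band is thereby reserved for the
noise model. Noise is additive: a sub-1.5 Hz sinusoidal baseline, white
Gaussian rescaled so the realized SNR is exact, and a 50/60 Hz powerline
sinusoid.

This emulates exactly what the pipeline contracts need — sampling
geometry, per-beat labels, class-distinct morphology, separable noise
families — and deliberately not the physiology: no heart-rate
variability beyond fixed prematurity, no multi-lead correlation, no
beat-to-beat morphological drift, no non-stationary noise. Passing tests
therefore demonstrate that every stage implements its contract and that
the network can learn morphologically distinct classes; they do not
demonstrate clinical-grade accuracy on real recordings, which requires
the real database and the full training budget and is out of scope here.

## 7. Problem sizes used by the test and acceptance runs

The suites choose sizes so the full run fits comfortably on one CPU:
decomposition tests use records of 3–20 s with ensembles of 6–20 (the
package default stays 50); the denoising property test runs 20 seeded
trials of 3 s at 5 dB input SNR; the one-batch overfit drives the
full-size dual-channel network on 32 samples with dropout 0 and learning
rate 0.002 (Adam at the default 0.0007 also converges, just in more
steps than the 200-step budget), stopping when the loss crosses 0.01;
pipeline smoke runs use a scaled-down network (128-point slices, 48×48
images) over two-minute synthetic records. The acceptance script runs
SMOTE at the published class sizes on full 1800-dimensional vectors.

## 8. Known limitations

* The 1.5 Hz cleaning rule removes whatever genuine signal content lies
  below 1.5 Hz; for rhythms whose sub-1.5 Hz content is substantial
  (irregular ectopy-heavy rhythms at low heart rates) a cut adapted to
  the measured rhythm spectrum would be a natural extension.
* The WFDB reader covers format 212 with one or two leads and beat-level
  annotations — the subset the pipeline consumes — not multi-segment
  records or other storage formats.
* Training the full network to published-accuracy scale is out of scope:
  the package's network is exact in architecture but tested at smoke
  scale.
* SMOTE neighbor search is exact; for corpora far larger than the
  published class sizes an approximate-neighbor backend would be needed.
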