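---
title: "Adaptive P300 decoding and tabletop perception: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive P300 decoding and tabletop perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assistbci)
```

`assistbci` is the computational core of an intention-driven assistive
drinking robot, rebuilt hardware-free: a brain–computer interface decodes
which of four speller keys (`cup1`, `cup2`, `cup3`, `back`) a user attends
to from their EEG, a depth-camera perception stack finds and localizes the
beverage containers on the table, and a decision layer sequences delivery
and return. Every sensor is replaced by a generative model, so the whole
loop runs — and is tested — on a desk.

This vignette documents the science, the tunable parameters and their
defaults, what the synthetic generators do and do not emulate, and the
design decisions taken where the problem left the design open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The speller paradigm

The speller shows 4 keys. In each *round* (1.2 s) every key flashes exactly
once, in random order, with a 200 ms inter-stimulus interval and 100 ms
stimulus duration. A *trial* — the selection of one symbol — spans several
rounds; a *session* is N trials. Attending a key makes its flashes rare
targets among distractors (an oddball paradigm), eliciting a P300: a
positive event-related deflection over parietal/occipital cortex roughly
300 ms after the attended flash. EEG is sampled at 250 Hz on 30 scalp
channels; each flash is analyzed through a 600 ms epoch (150 samples).

`session_timing()` holds these constants and the online stopping bounds
`m_min = 3`, `m_max = 8`.

### The synthetic EEG world

`synthesize_recording()` adds a topography-weighted template to the
trial-target flashes only, on top of structured background noise:

* **Template**: a positive half-cosine bump of 200 ms width peaking at
  `p300_latency` (default 0.3 s) — canonical monophasic P300 morphology
  with every shape parameter explicit. Per-event Gaussian latency jitter
  (sd 20 ms) models trial-to-trial variability.
* **Amplitude**: default 5 µV against 10 µV noise, a realistic
  single-trial SNR for a naive subject; "high-SNR" study sessions use
  10 µV against 5 µV noise.
* **Topography**: weight 1.0 on P7/P3/Pz/P4/P8/O1/Oz/O2, 0.3 elsewhere,
  reflecting the parietal/occipital generators of the P300.
* **Noise**: AR(1) with coefficient 0.95 mixed 1:1 in power with white
  noise — an inexpensive approximation of the 1/f character of spontaneous
  EEG. `white` and `pink` (spectrally shaped) alternatives are selectable.

What the generator does **not** emulate: eye-movement and muscle
artifacts, inter-channel noise correlation, non-stationarity across a
session, and subject-specific latency/topography differences. A green
decoding test therefore establishes the correctness and calibration of the
*pipeline*, not human-subject performance; the headline human numbers of
the original system are out of reach by construction.

## Preprocessing

Each channel is band-passed to 0.1–20 Hz with a 4th-order Butterworth
filter (scipy/Matlab order convention: an 8-pole bandpass), applied
forward-only — zero-phase filtering would be acausal for an online loop.
Because no DSP package is assumed, the filter is designed from first
principles (analog prototype → lowpass-to-bandpass transform → bilinear
transform) and applied as cascaded second-order sections; with a 0.1 Hz
edge at 250 Hz a single 8th-order polynomial is numerically fragile, SOS is
not. The design was cross-checked against an independent reference
implementation during development; the frozen behavioral bounds (<3 dB at
10 Hz, >20 dB at 50 Hz, DC rejection) live in the tests.

Epochs (600 ms, 150 samples) are then decimated by plain subsampling every
6th point — the bandpass has already suppressed content above the
decimated Nyquist (~20.8 Hz) — giving 25 samples per channel, and
concatenated channel-major into feature vectors of length
P = 30 × 25 = 750. No baseline correction is applied (none is part of the
stated pipeline). Per-key feature vectors are averaged across the rounds
seen so far; averaging M rounds scales the noise variance by 1/M while
preserving the event-locked component.

## Bayesian linear discriminant analysis

Epoch labels t ∈ {−1, +1} (target / non-target) are regressed onto
bias-augmented features x under a Gaussian likelihood with noise precision
β and a zero-mean Gaussian prior with precision α on the P feature weights
and a near-flat precision ε (default 1e-10) on the bias weight. The
posterior is Gaussian:

$$m = \beta\,(\beta X X^\top + I'(\alpha))^{-1} X t,\qquad
  C = (\beta X X^\top + I'(\alpha))^{-1},$$

with $I'(\alpha) = \mathrm{diag}(\alpha,\dots,\alpha,\varepsilon)$. The
hyperparameters follow MacKay's evidence fixed point: with eigenvalues
$\lambda_i$ of the feature-block $XX^\top$,
$\gamma = \sum_i \beta\lambda_i/(\beta\lambda_i+\alpha)$,
$\alpha \leftarrow \gamma / \lVert m_{\text{features}}\rVert^2$,
$\beta \leftarrow (Q-\gamma)/\lVert X^\top m - t\rVert^2$, iterated from
α = β = 1 until the relative change drops below 1e-6 (cap 500). The bias
slot is excluded from γ and from α's norm; including it would let a single
unregularized coordinate contaminate the effective-dimensionality count.
Prediction uses the predictive mean $\mu = m^\top \hat x$ (the decision
statistic) and variance $\sigma^2 = 1/\beta + \hat x^\top C \hat x$.

The fit is validated two ways that never share code with the fitting path:
a dense linear solve at fixed (α, β), and closed-form ridge regression in
the ε = α special case.

## Self-adaptive decoding and the stopping threshold

Online, the decoder consumes rounds one at a time: per-key round-averaged
features are scored by the predictive mean, and the four scores are
normalized to

$$S_i = \frac{\mu_i - \min_j \mu_j}{\sum_j (\mu_j - \min_j \mu_j)},$$

which is shift-invariant, sums to 1, and — crucially — leaves the maximum
informative. (A plain min–max rescale would pin max S at 1 every round and
make any threshold vacuous; this is the package's resolution of an
underdetermined normalization, flagged as such.) The trial stops with
decision argmax S as soon as `M >= m_min` and `max S >= theta0`, or
forcibly at `M = m_max`; ties break to the lowest key id and are flagged.
Whether the top score or the top-two margin should face the threshold is
not determined by the source design; max S is used and the margin variant
noted as an alternative.

Selection time is `M * t_round`, excluding inter-trial pauses — the
accounting under which a perfect 4-way selection at θ0 = 0 (3 rounds,
3.6 s) yields the Wolpaw information transfer rate

$$\mathrm{ITR} = \frac{60}{t}\Big(\log_2 K + p\log_2 p +
  (1-p)\log_2\tfrac{1-p}{K-1}\Big) = 33.33\ \text{bits/min},$$

the worked consistency check carried in the acceptance suite.
`select_threshold()` scans a θ0 grid (default 0–0.95 by 0.05), computes
accuracy and ITR on the same data, and picks the smallest θ0 whose
accuracy first attains the grid maximum, since ITR only falls as θ0 rises.

One behavioral subtlety the synthetic study exposed: the stopping rule is
only informative when the threshold binds. At low θ0 every trial stops at
`m_min` regardless of signal quality, and at zero amplitude pure noise
crosses low thresholds spuriously; the SNR study therefore evaluates the
monotone accuracy / mean-M trends at θ0 = 0.9, inside the binding regime.

## Tabletop perception

### Scene synthesis

`synth_scene()` renders an organized point cloud (an H×W grid of 3D
camera-frame points preserving pixel adjacency, the native output format
of RGB-D sensors) by per-pixel ray casting from a pinhole camera looking
straight down at a table plane bearing cylinders and boxes. Defaults:
160×200 grid, focal length 180 px, table at 0.8 m — container-sized
objects then span 7–11 px in radius, a realistic working scale. Optional
Gaussian depth noise acts along rays.

Ground truth comes in two flavors: `raw_labels` is the exact geometric
truth (plane / object-i / miss), used by geometric oracles; `labels`
additionally voids a 2-px band around every class boundary (NA). The void
band is the standard segmentation-benchmark convention for pixels whose
class is ill-defined at sensor resolution — and it is physically honest:
structured-light depth cameras are unreliable exactly at occlusion
boundaries. It matters here because the normal estimator below *cannot*
classify those pixels even in principle, so scoring them would measure the
convention, not the algorithm.

### Plane extraction and two-times region growing

Surface normals are cross products of the two 4-neighbor pixel-grid
difference vectors, unit-normalized; border pixels and pixels with an
invalid neighbor get no normal. The horizontal background plane is grown
from seeds with near-vertical normals (tolerance 10°): a neighbor joins
when its own normal is near-vertical and it lies within
`d_threshold = 0.02 m` (3D Euclidean) of the point it grows from;
queue-based, each pixel enqueued once; regions of at least `n_C = 500`
pixels are accepted. The tolerance and size thresholds are not dictated by
the source design; these defaults suit the rendered scale and are exposed.
Growth uses 4-connectivity, matching the normal stencil; 8-connectivity is
a flag.

Object candidates are connected components of valid non-plane pixels
enclosed by the plane footprint (bounding-box test — this is what rejects
the open ring of no-normal pixels that borders the table from outside),
and their pixel-space convex hulls delimit the search regions. The
two-pass growth then runs per hull: pass 1 takes every valid in-hull
non-plane pixel as an interior point (sets below `n'_C = 50` rejected);
pass 2 seeds from interior points on the hull boundary and grows outward
across the hull under the same distance rule, iterated to closure — so an
object part protruding past its hull is recovered in full. Point-in-polygon
counts the boundary as inside, because pass-2 seeds live on the hull.
Whether outward growth should be capped at one ring rather than iterated
to closure is left open by the source; closure is used, and on fixtures it
provably equals the exhaustive flood fill of the object's component.
Objects are localized as the coordinate-wise mean of their member points.

### Frames

`rigid_transform` objects map points homogeneously (p' = Rp + T) between
the camera, calibration-board, and robot frames; inversion and composition
carry the frame labels and are checked against independent 4×4
homogeneous-matrix algebra. Calibration itself (how R, T are measured) is
out of scope; transforms load from a JSON frame graph.

## The recognizer

The crop classifier is the four-stage convolutional network: 3×3
same-padded convolutions with 32/64/128/256 kernels, each followed by ReLU
and 2×2 max-pooling, then fully connected stages 256/128/64/4 with dropout
0.5 between the last two and a 4-way softmax. Same-padding is chosen so
pooling halves sides cleanly (200 → 100 → 50 → 25 → 12 at full scale); the
kernel counts then fix every parameter count (first conv:
32·3·3·3 + 32 = 896). No autodiff stack exists in this environment, so
convolutions run as im2col matrix products against BLAS with hand-derived
gradients, optimized by Adam (lr 1e-3, batch 32 — conventional defaults,
exposed). Training is deterministic given a seed; inference disables
dropout and is bit-reproducible.

Training data are procedurally rendered silhouettes (squat cylinder = can,
tall cylinder + neck = bottle, cylinder + handle = cup, textured patch =
background) with pose, size, color and illumination jitter, split 7:3
stratified. Augmentation adds a horizontal mirror and a spatial rescale of
every crop ("rescaling" is read as spatial scaling; intensity rescaling is
the noted alternative). These synthetic crops exercise the full
train/predict path; they do not stand in for real camera imagery, and the
recognizer's acceptance bar is deliberately property-based (overfitting 80
crops at 32×32 scale), not a real-data accuracy claim.

## The decision layer

`run_e2e()` wires the pieces into drinking tasks: two decoded commands per
task (choose a container; send it back), segmentation + localization of
the commanded container, camera → board → robot transformation, and a
guarded state machine (deliver only from idle and only for a located
object; back only while holding; invalid commands are rejected and logged
rather than guessed — the source leaves this case undefined). Robot motion
is simulated as a fixed-duration waypoint traversal; timing bookkeeping
uses the decoder's round accounting. The commanded object is matched by
scene order (centroids sorted along x) by default; a trained recognizer
can be plugged in, but the end-to-end contract does not depend on it and
the pure-R network is the one expensive component.

## Numerical choices and degenerate inputs, collected

* Filter: SOS cascade, forward-only; coefficients from the bilinear
  transform with pre-warped edges; unit gain pinned at the warped center
  frequency.
* BLDA: Cholesky solves; eigendecomposition of the feature-block
  $XX^\top$ computed once per fit; singular systems raise an error
  advising a larger ε/α floor; single-class labels are rejected.
* Normalization: all-equal scores return the uniform vector 1/K.
* Region growing: each pixel enqueued once (termination is structural);
  accepted sets are invariant to scan order.
* Ties: argmax ties break to the lowest key id, deterministically, and
  are flagged in the decoder state.
* Empty sets: locating an empty point set, averaging an empty feature
  list, and an empty θ0 grid are errors; an event-free recording is valid.
* Serialization: recordings and models round-trip losslessly through
  plain text (`%.17g`).

## Known limitations

The generators are the package's world: no artifacts or non-stationarity
in the EEG, no sensor noise model beyond ray-depth jitter in the clouds,
no real imagery for the recognizer. Decoding results calibrate the
machinery, not humans. The recognizer at full 200×200 scale trains only
slowly in pure R (it is built and audited at that scale, trained at
reduced scale). Camera calibration, mouth tracking and robot kinematics
are explicitly out of scope.
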