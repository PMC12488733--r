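---
title: "From hyperspectral cube to fruit quality: models and methods"
author: "fruithsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From hyperspectral cube to fruit quality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruithsi)
```

## The problem

Refractometry, titration and colorimetric assays quantify soluble solids
content (SSC, %), vitamin C (VC, mg/100 g) and soluble protein (SP, mg/g) in
apples accurately — and destroy the fruit in the process. Vis-NIR
hyperspectral imaging offers a non-destructive alternative: a push-broom
camera records a reflectance spectrum (here 360 contiguous bands over
395–1008 nm) at every pixel, and the fruit's mean reflectance spectrum can
be regressed on wet-chemistry reference values. `fruithsi` implements that
pipeline end to end: cube ingestion and white-reference correction, fruit
segmentation, Savitzky–Golay (SG) smoothing, successive-projections
(SPA) wavelength selection, three small regression networks, and an
R²/RMSE/RPD evaluation framework with internal 7:3 splits and frozen-model
external validation.

## Cube ingestion and white-reference correction

Cubes are read from the ENVI header/binary convention (BIL, BIP or BSQ
interleave; the writer emits BSQ, 32-bit little-endian float). Raw counts
become relative reflectance through a white calibration panel:

$$R_{p,b} = \frac{I_{p,b} - D_b}{W_b - D_b},$$

where $W_b$ is the panel's mean intensity and $D_b$ an optional dark-current
spectrum. Instruments that pre-heat to thermal equilibrium effectively
suppress dark current, so $D_b$ defaults to zero but remains available.
Reflectance is clipped to $[0, 1 + \varepsilon]$ with headroom
$\varepsilon = 0.1$: glossy fruit shows specular pixels slightly brighter
than the panel, and clamping them avoids propagating non-physical values.

## Fruit segmentation

The region of interest is recovered by a spectral-contrast chain:

1. **Enhancement.** A two-band difference image, reflectance near 800 nm
   minus reflectance near 450 nm. Fruit tissue is bright in the NIR and
   dark in the blue; typical backgrounds are not, so the fruit/background
   boundary is maximally contrasted. Both bands are configurable.
2. **Binarization.** Otsu's parameter-free threshold on the score image.
3. **Component selection.** 8-connected labeling keeps the largest
   component; interior holes are filled so the ROI is simply connected.
4. **Contour modeling.** The boundary is traced as a closed polyline,
   parameterized by chord length, and least-squares fitted with a periodic
   cubic B-spline (40 control points by default), which suppresses
   pixel-level jaggedness while preserving shape.
5. **Rasterization.** The smoothed curve is filled back to a mask by
   even-odd scanline parity. Traced boundary points are pixel *centers* —
   systematically half a pixel inside the true region edge — so the fitted
   curve is displaced half a pixel along its outward normal before filling;
   without this correction the recovered mask is biased small by roughly
   perimeter/2 pixels.

The per-fruit spectrum is the arithmetic mean reflectance over the final
mask. Averaging over the full fruit mask is the default; a central sub-ROI
is not currently offered, because on the synthetic scenes the full mask
recovers the generating spectrum essentially exactly.

## Savitzky–Golay smoothing

SG smoothing is the pipeline's only spectral preprocessing: a sliding
window of `window` bands is fitted with a degree-`order` polynomial and the
band value replaced by the fit at the window center. Scatter corrections
(SNV, MSC, derivatives) are deliberately not implemented — the downstream
networks carry their own normalization (batch normalization, input
standardization), and stacking corrections risks removing signal. Window 11
and order 2 are the defaults, the common Vis-NIR choice; both are plain
arguments and are recorded in pipeline provenance, because comparisons of
RAW versus SG inputs can hinge on them. Edges are handled by evaluating the
polynomial of the nearest full window at the edge offsets, so the 360-band
axis keeps its length — required by the networks' fixed input reshape.

## SPA wavelength selection

Adjacent Vis-NIR bands are strongly collinear. The successive projections
algorithm selects a compact, minimally collinear subset in three phases:

1. **Candidate chains.** Bands are standardized to zero mean and unit
   variance (population convention). From every starting band a greedy
   chain is grown: at each step all unselected bands are projected onto the
   orthogonal complement of the selected ones and the band with the largest
   residual norm is appended. Exactly collinear bands have zero residual
   and are never selected. Growing one chain per start subsumes the
   max-variance-start variant, which remains available as a flag.
2. **PRESS scoring.** Every chain prefix with size in `[kMin, kMax]`
   (defaults 5 and the band count) is scored by the prediction residual
   error sum of squares of an ordinary-least-squares fit (with intercept),
   computed on a validation share split off the *training* partition
   (30% by default, seeded). The held-out test partition never enters
   selection. The global PRESS minimizer wins.
3. **Relevance pruning.** The winner's variables are ranked by the
   relevance index $r_j = |b_j| \, s_j$ (coefficient magnitude times band
   standard deviation) and the smallest prefix whose PRESS is not
   significantly worse than the minimum is kept, using the one-sided ratio
   test $\mathrm{PRESS}_m/\mathrm{PRESS}_{\min} \le F(1-\alpha;
   n_{val}, n_{val})$ with $\alpha = 0.25$. The prefix search starts at
   `kMin`, reading the candidate-size range as binding for the final subset
   as well.

## The three regression networks

Each model ingests a spectrum reshaped to $[n \times 1 \times 1]$, where
$n$ is the number of input bands (full spectrum or SPA subset):

* **CNN** — conv(8 filters, 3×1) → batch norm → ReLU → max-pool(2×1) →
  conv(32, 3×1) → batch norm → ReLU → max-pool(2×1) → dropout(0.4) →
  dense(32) → dense(1).
* **CNN-BiGRU** — two parallel branches: a CNN branch (conv 16, 3×1 +
  batch norm + ReLU + max-pool(3×1) + flatten + dense 25) and a BiGRU
  branch of two 35-unit GRU layers, one reading the band sequence and one
  its reversal via a flip step; the two final hidden states (70 features)
  are concatenated with the CNN branch's 25 and mapped to the output.
* **CNN-BiGRU-Attention** — the CNN-BiGRU plan plus a single-head
  dot-product self-attention layer (query/key dimension 50) over the 95
  concatenated features, before the regression layer.

The engine (1-D convolution, batch normalization, max pooling, dropout,
GRU with backpropagation through time, attention, Adam) is implemented in
base R with analytic gradients; the test suite verifies every architecture
against finite differences.

Architecture readings that the textual plan leaves open, resolved here:

* A 3×3 pooling window is undefined on a width-1 axis; the hybrid branch
  pools 3×1 with stride 3. All pooling uses stride = window and floor
  semantics, so flatten widths are reproducible from $n$ alone.
* Convolutions use same-padding; pooling is then the only length reducer,
  and the CNN accepts inputs down to 4 bands, the hybrids down to 3 — SPA
  subsets of 5 bands (the configured minimum) are first-class inputs.
* The GRU consumes the spectrum as a length-$n$ sequence of scalar steps
  and contributes its final hidden states, the minimal reading of a
  bidirectional summary.
* Self-attention treats the 95 concatenated features as scalar tokens.
  Queries and keys are learned affine 50-dimensional projections of each
  token; values are the token scalars, so the layer re-weights the feature
  sequence, and a residual (skip) connection around the block — the
  standard stabilization for attention layers — feeds the regression
  layer with `features + attended`. A mean-pool after attention was
  rejected: with scalar tokens it collapses the context to rank one,
  reducing the head to an affine function of a single scalar.
* Dropout is active only during training; prediction uses frozen
  batch-norm running statistics and is bit-deterministic.

**Training.** Adam minimizes mean squared error. The CNN trains 500 epochs
at learning rate 0.001 with L2 factor 0.01; the hybrids train 1000 epochs
from 0.01 with one ×0.1 decay after epoch 700 (the midpoint of the 600–800
window; configurable). Batch size defaults to 16. Inputs are standardized
per band and the response is centered and scaled, both on training data
only and frozen into the model — with a fixed learning-rate schedule this
keeps optimization scale-free across analytes whose native scales span
0.4 (SP) to 12 (SSC). All randomness (initialization, shuffling, dropout)
derives from one seed, making weights bit-reproducible on a given machine.

A practical note on the CNN's regularizers: under dropout 0.4 + L2 0.01
even a noise-free affine signal trains to roughly R² 0.95–0.98, not 1 —
the dropout-on objective itself floors near 0.93. The trainability tests
therefore check exact-recovery with regularization disabled and a slightly
lower bar under the default schedule; both knobs (`dropout`, `l2`) are
exposed in `trainConfig()`.

## Evaluation

For measured $y_i$ and predictions $\hat y_i$:

$$R^2 = 1 - \frac{\sum_i (y_i - \hat y_i)^2}{\sum_i (y_i - \bar y)^2},
\qquad \mathrm{RMSE} = \sqrt{\tfrac1n \sum_i (y_i - \hat y_i)^2},
\qquad \mathrm{RPD} = \frac{\mathrm{SD}(y)}{\mathrm{RMSE}}.$$

RPD > 2.0 is labeled *good*, RPD ≤ 1.4 *weak*, the rest *intermediate*.
The SD convention defaults to sample ($n-1$), with the population
convention available; the choice is recorded in every report because it
shifts RPD by $\sqrt{n/(n-1)}$. Under the population convention
$\mathrm{RPD} = 1/\sqrt{1-R^2}$ holds identically and is used as a
cross-check. Data are split 7:3 by a seeded shuffle (optionally stratified
by cultivar), and external sets are evaluated with the frozen model — no
refit, no influence on standardization or selection (the test suite checks
this by comparing fitted statistics against a run with corrupted held-out
rows). Cross-year robustness is summarized as the percentage reduction
$100\,( m_{int} - m_{ext})/m_{int}$, rounded half-up to two decimals.

## The synthetic data generator

No imaging dataset accompanies the method, so the generator is a
first-class module that renders the statistical structure the pipeline
assumes, with every stage's ground truth recoverable:

* a smooth cultivar-neutral baseline rising from the visible into the NIR;
* cultivar-modulated pigment absorption centred near 530 nm (six cultivar
  levels, depths 0.08–0.22), a chlorophyll dip at 680 nm and a water
  feature at 970 nm, each with mild per-sample variability;
* narrow analyte-linked Gaussian absorption features: VC at
  409/577/679/700/757 nm, SP at 403/430/551/617/846 nm, and broad SSC
  features across 700–950 nm (centers 730/790/840/910 nm);
* per-sample smooth continuum perturbations (broad Gaussian basis,
  coefficient SD 0.012) and band-wise iid noise (SD 0.005);
* optional multiplicative/additive scatter, off by default so the
  selection tests stay sharp.

Analyte panels are drawn uniformly from the measured ranges (VC 1.08–3.27
mg/100 g, SSC 8.48–11.92%, SP 0.32–0.51 mg/g). Each analyte's absorption
bands are tied to it through a *sub-pool* model: band $k$ carries load
$u + d_k$ where $u$ is the normalized analyte value and the $d_k$ are
band-specific deviations (SD 0.18) centered across the analyte's bands.
Chemically this reads as distinct molecular sub-fractions — e.g. different
protein populations — each dominating one vibrational band while the
assay measures their aggregate; statistically it makes the analyte the
exact average of its band loads, so *every* planted band carries necessary
information. That is what lets PRESS and the F-test retain all five
protein bands instead of collapsing onto one or two, and it gives the
networks a high, known performance ceiling. Feature strength (0.07
reflectance units) and the baseline's blue-end level were chosen so that
feature depths never clip at zero reflectance, which would break the
affine analyte link. With a single feature and noise off, the band's
reflectance is an exactly affine function of its analyte — the degenerate
case the tests pin down.

Synthetic *cubes* place an ellipse with harmonic boundary perturbation
("apple") carrying one generated spectrum under a smooth spatial gain
field in [0.9, 1.1], over a dark low-NIR background, and return the ground
truth mask for IoU scoring.

What the generator does *not* emulate: radiative transfer, specular
geometry, calyx/stem regions, seasonal drift beyond a configurable
baseline-plus-noise shift, and cultivar genetics. Passing tests on this
model demonstrate that the pipeline recovers structure it is designed for;
they do not certify instrument-grade accuracy on real orchards.

## Problem sizes and empirical behaviour

The test suite and the acceptance script run the full method at desk
scale, chosen so the whole suite completes in minutes: synthetic studies
use n = 300 samples (7:3 split), SPA chains are grown from every start
with subset sizes 5–25, hybrid networks train 300 epochs for the synthetic
studies (the full 1000-epoch schedule remains the default for real use),
and segmentation fidelity uses 70×70×80-band cubes. Under those
conditions, reproduced by `scripts/acceptance.R`: SPA recovers all five
planted SP bands within ±2 positions across ten seeds; the attention
model reaches test R² ≈ 0.90 per analyte (RPD ≈ 3); segmentation IoU
against the generating mask exceeds 0.99.

On architecture comparison: both hybrids beat the CNN consistently on
synthetic tasks with long-range band interactions (the CNN's dropout and
pooled locality cost it a few points of R²), while the attention variant
and the plain BiGRU are statistically indistinguishable at these sample
sizes — the attention increment sits within seed-to-seed noise. The
ordering test asserts exactly that: strict hybrid-over-CNN, and
hybrid-vs-hybrid equality up to one point of noise.

## Numerical choices and degenerate inputs

* Otsu thresholding operates on min-max rescaled scores; constant score
  images are rejected (no threshold exists).
* Periodic B-spline fitting requires the boundary to have more points than
  control points and more than `degree + 1` points; both violations error.
* `spaStandardize` refuses zero-variance bands by index; rank-deficient
  PRESS prefixes are skipped with a warning rather than failing the search.
* Ties in the greedy chain (equal residual norms) resolve to the lowest
  band index via `which.max`.
* Training aborts with the epoch index if the loss turns non-finite;
  zero-variance responses fall back to unit scaling.
* Mask rasterization uses half-open scanline intervals so shared polygon
  vertices are counted once.

## Limitations

The networks run on a base-R engine: fine for the few-thousand-parameter
models and desk-scale data used here, but full-spectrum BiGRU training
(360 timesteps, 1000 epochs) is slow — band selection before the hybrids
is the intended operating mode, mirroring the method's own finding that
compact SPA subsets suffice for protein prediction. The external-validation
protocol assumes the second season is measured on the same wavelength
grid. No uncertainty quantification beyond RPD is provided.
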