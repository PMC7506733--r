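---
title: "Reconstructing ultrasound echogenicity maps from speckled B-mode images"
author: "EchoMap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ultrasound echogenicity maps from speckled B-mode images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EchoMap)
```

## The problem

B-mode ultrasound forms an image from the envelope of coherently summed
echoes. When many sub-wavelength scatterers fall inside a resolution cell,
the complex echo amplitude is circularly Gaussian and its envelope is
Rayleigh distributed: the image is corrupted by *speckle*, a granular,
multiplicative noise whose grain size is set by the system point spread
function (PSF). Speckle hides the quantity a clinician actually cares
about — the intrinsic tissue reflectivity, or *echogenicity map* — and the
finite PSF blurs structure boundaries.

EchoMap implements a simulation-trained convolutional approach to this
inverse problem: because ground-truth echogenicity is never available for
real tissue, training pairs are generated *in silico* from a forward
speckle model matched to the PSF of the target imaging system, and a
residual U-net is trained to map the speckled B-mode image back to the
echogenicity map. Classical despeckling filters (non-local means,
anisotropic diffusion, bilateral) and a CR/CNR/FWHM/MSE/PSNR/SSIM/MI
metric suite are included for comparison.

## Forward model

For an echogenicity map $X$ (linear amplitude, background fixed at 1.0),
the simulator draws a complex scatterer field $Z$ with i.i.d. standard
normal real and imaginary parts, forms the complex reflectivity $X \odot
Z$, convolves it with a separable 2-D Gaussian amplitude PSF $k$
(zero-padded, same-size output), and takes the modulus:

$$ B \;=\; \lvert (X \odot Z) \ast k \rvert . $$

Taking the modulus *after* convolution is the standard convolution model
of speckle formation and produces fully developed Rayleigh speckle: in a
homogeneous region of amplitude $a$ each output component is Gaussian
with variance $a^2 \lVert k \rVert_2^2$, so the envelope is Rayleigh with
scale $a\lVert k\rVert_2$, mean $a \lVert k \rVert_2 \sqrt{\pi/2}$ and
point SNR (mean/sd) $\sqrt{\pi/(4-\pi)} \approx 1.9131$ regardless of $a$
or $k$ (`simulateBmode`, `speckleSnrTheoretical`). An option flag exposes
the literal amplitude-domain variant (modulus before convolution) for
comparison; it is not the default because it destroys the Rayleigh
statistics.

PSF *size* is specified per axis as the full width at $-6$ dB of the
amplitude PSF — the same level at which the wire-based estimator measures
it — so the Gaussian standard deviation is $\sigma = \mathrm{size} /
(2\sqrt{2\ln 2}) \approx \mathrm{size}/2.3548$ (`PSFSpec`,
`gaussianPsfKernel`). The kernel has peak 1 and odd support covering $\pm
3\sigma$. The model assumes a spatially invariant PSF; depth-dependent
blur is out of scope.

### Testing the speckle statistics

Neighbouring envelope pixels are correlated over the PSF scale, so a
Kolmogorov–Smirnov test that assumes i.i.d. draws rejects intermittently
if fed raw pixel grids even when the marginal distribution is exactly
Rayleigh. The test suite therefore checks the Rayleigh hypothesis on
background pixels decimated on a 6-px grid (beyond the correlation length
of the PSFs used), with at least $10^4$ near-independent draws pooled
from $512^2$ homogeneous fields (`rayleighKsTest`).

## Phantom generator

`generateEchogenicityMap` places three structure kinds on a unit
background: circular contrast regions ("cysts"), hyperechoic rectangles
("edges") and single-pixel point reflectors ("wires"). Echogenicity is
expressed in dB relative to background; the training grid crosses seven
cyst levels $\{\pm 6, \pm 18, \pm 30, \text{anechoic}\}$ with four shared
edge/point levels $\{+3, +6, +12, +20\}$, giving the 28 combinations
enumerated by `levelCombinations` (anechoic is encoded as $-\infty$ dB so
that $10^{\mathrm{level}/20}$ evaluates to amplitude 0). All cysts in a
map share the combo's cyst level and all edges/points share its
edge/point level.

Design choices where the construction was open:

* **Overlap policy.** Placements are rejection-sampled; a new structure
  must clear existing ones by 2 px so every pixel carries exactly one
  level and the ground truth stays unambiguous. After a bounded number of
  failed attempts a placement error is raised (the dataset builder
  retries with a derived seed).
* **Counts and sizes.** Per map: 1–3 cysts, 1–2 edges, 1–4 points
  (uniform). Cyst radii are uniform on $[8, 40]$ px and edge sides on
  $[10, 60]$ px at the reference 256-px image side; the defaults scale
  proportionally with the image side so that smaller phantoms remain
  placeable. All of these are configurable arguments.
* **Margin.** Structures keep 8 px clear of the border, so zero-padding
  boundary artifacts of the simulator never touch annotated regions.
* **Axes.** Matrix rows are axial (depth), columns lateral, everywhere in
  the package.

## Normalization: two conventions

Training pairs are normalized to $[0, 1]$ (`normalizePair`):

* `"max"` — each image divided by its own maximum. Because the speckle
  maximum overshoots the Rayleigh mean by a factor that grows with the
  number of resolution cells, the normalized B-mode *background* lands
  well below the normalized ground-truth background: an amplitude gap.
  A network trained to close that gap brightens backgrounds, i.e.
  overestimates echogenicity.
* `"theoretical"` — the ground truth is divided by its maximum amplitude
  $A_{max}$, while the B-mode image is divided by the *expected* envelope
  level corresponding to that maximum, $R = A_{max} \lVert k \rVert_2
  \sqrt{\pi/2}$ (the Rayleigh envelope mean for a region at peak
  echogenicity), then clipped to $[0,1]$. Backgrounds of input and target
  then coincide in expectation, removing the incentive to overestimate.

The "theoretical reference" is named but not fully specified in the
source method; $R$ above is this package's reading (the natural
population counterpart of the per-image maximum), and the acceptance
suite verifies that it closes the background gap to within sampling
error while `"max"` leaves the B-mode background at roughly half the
truth level.

The network always trains on *linear* normalized amplitudes; log
compression (`logCompress`, default 60 dB dynamic range mapped to 8-bit)
is a display and metric-domain operation only.

## The residual U-net

`buildUnet` constructs a five-block encoder (block 1: three same-padded
convolutions; blocks 2–5: 2×2 max-pool then three convolutions, each
convolution followed by batch normalization and ReLU) and a four-block
decoder (2×2 stride-2 transpose convolution halving the channels,
concatenation with the equal-size encoder output, then two
convolutions). Feature counts are `minFilters * 2^k`, k = 0..4, so
`minFilters = 32` gives 32–512 channels. A final 1×1 convolution emits a
residual $r(x)$ and the model output is $f(x) = r(x) + x$.

Choices on points the architecture description leaves open:

* Decoder convolutions also use batch norm + ReLU (symmetry with the
  encoder); the transpose convolutions do too.
* Only the transpose (2×2) and output (1×1) kernels are fixed; all other
  convolutions use the configured `filterSize` (3, 5 or 7).
* The residual head is zero-initialized, so an untrained network is
  exactly the identity mapping. This makes small-data smoke training
  start from a sensible operating point instead of a random one.
* All convolutions are "same"-padded; inputs must have sides divisible by
  16 (four poolings), and `despeckle` reflect-pads then crops other
  sizes.

### Losses and optimization

Two training options (`trainingConfig`):

* **Mixed loss** $L_{mixed} = L_{\ell_1} + \beta\, L_{MS\text{-}SSIM}$
  with $\beta = 300$ by default and $L_{MS\text{-}SSIM} = 1 -
  \mathrm{MSSSIM}(f(x), y)$, optimized with Adam at a constant learning
  rate.
* **MSE loss**, optimized with Adam under a step-decay schedule. "Step
  decay" names a schedule rather than an optimizer; the package halves
  the learning rate every 10 epochs, a conventional reading, and logs the
  effective rate.

MS-SSIM uses the standard five-scale construction (11×11 Gaussian
window, $\sigma = 1.5$, 'valid' support, 2×2 mean-pool between scales,
weights 0.0448/0.2856/0.3001/0.2363/0.1333). When the image is too small
for five scales the construction truncates to the largest supported
count and renormalizes the weights — 64-px images support three scales.
Scale means are clamped below at $10^{-4}$ before the weighted geometric
product so the index stays differentiable on pathological inputs.

The network kernels (convolution via im2col + GEMM, pooling, transpose
convolution, batch normalization) are implemented natively with analytic
backward passes, and the MS-SSIM gradient is derived in closed form and
backpropagated through the windows and the scale pyramid; every backward
pass is verified against central finite differences in the unit tests.
Adam uses $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$.
Batch-norm running statistics use momentum 0.9 and biased variances.
Training shuffles minibatches of 8 each epoch from seeds derived from the
configuration seed; identical seeds reproduce identical runs.

## PSF estimation from wire targets

`estimatePsfSize` implements the three-step recipe used to match the
simulator to a target system: locate the dominant peak in each
user-chosen wire ROI, take the axial and lateral profiles through the
peak, find where they cross $-6$ dB relative to the peak, and average the
crossing distances over ROIs. Profiles are upsampled 16× with a cubic
spline before the crossings are located by linear interpolation on the
dense grid; this gives the sub-pixel resolution that fractional-pixel PSF
sizes (e.g. 6.2 px lateral) require. Log-compressed inputs are
linearized first using the known display mapping, since the threshold is
defined on amplitude. An optional 3×3 mean filter can be applied *for
peak picking only* (widths are still measured on raw profiles), as a
guard against isolated speckle spikes.

On an isolated wire over an anechoic background the envelope is exactly
|scatterer| × kernel, so the estimator's accuracy can be checked against
the programmed sizes; the acceptance suite requires mean absolute error
at or below 0.5 px per axis over 20 seeded simulations for sizes
including (6.2, 2.8).

## Classical baselines

Three standard despeckling filters operate on the 8-bit display-domain
image (the conventional setting for post-processing log-compressed
B-mode images):

* **NLM** — patch 7, search window 21. The default strength is $h = 0.8
  \hat\sigma$ where $\hat\sigma$ is the median of 8×8-block population
  standard deviations (derivative-based noise estimators collapse on
  PSF-correlated speckle), combined with the standard $2\sigma^2$ patch
  distance offset. An explicit $h$ selects the classic uncorrected
  weights, under which $h \to 0$ recovers the identity.
* **ADF** — Perona–Malik diffusion, 4-neighbour fluxes, replicated
  (Neumann) boundaries, 30 iterations, time step 0.2 (explicit stability
  requires $\le 0.25$), $\kappa = 30$ on the 8-bit scale, exponential or
  quotient conduction. The discrete scheme is conservative: the global
  mean is preserved to rounding error.
* **BLF** — Gaussian spatial (σ 3 px) × Gaussian range (σ 25 on the
  8-bit scale) weights, truncated at $3\sigma$ and renormalized over
  in-bounds pixels, so constant images are exact fixed points.

These defaults are conventional mid-strength settings chosen for the
qualitative comparison; no parity with any particular published
parameterization is claimed.

## Metric suite

All quantitative metrics follow their textbook definitions
(`contrastRatio`, `cnr`, `fwhm`, `mseMetric`, `psnrMetric`,
`ssimMetric`, `msSsimMetric`, `mutualInformationDiagonal`):

* CR is the signed difference of ROI means on the display-domain image;
  CNR divides it by the root-sum-square of the two population standard
  deviations (no absolute value — the sign carries information).
* FWHM takes the profile through the wire peak, subtracts the
  profile-endpoint baseline, and measures the half-maximum crossing
  distance. Two crossing conventions are exposed: `"spline"` (default,
  16× cubic-spline upsampling; accurate to well under 1% for Gaussian
  peaks with σ from 1 to 8 px) and `"linear"` (classic piecewise-linear
  convention, under which a single-pixel impulse has width exactly 1).
* MSE/PSNR/SSIM/MS-SSIM/MI are computed on 8-bit display images
  ($MAX_I = 255$); PSNR of identical images is reported as `Inf` rather
  than an error.
* The mutual information variant is deliberately the *diagonal-joint*
  histogram form $\sum_k P_{XY}(k)\log \frac{P_{XY}(k)}{P_X(k)P_Y(k)}$
  where $P_{XY}(k)$ is the fraction of positions at which both images
  equal $k$ — when the images coincide it equals the histogram entropy.
  A `full = TRUE` flag computes conventional full-joint MI for
  reference. The logarithm base defaults to 2 and is configurable, since
  the value scales with it.

`evaluateReconstruction` assembles all applicable metrics into a
`MetricsReport`; full-reference fields are `NA` without a ground truth,
and a washed-out wire yields `NA` FWHM rather than aborting a batch.

## Desk-scale study conditions

The reference configuration (350 pairs per combination = 9800 pairs of
256×256 images, 30 epochs, minFilters 32) is a GPU-scale workload. The
package's automated checks run a deliberately scaled-down version of the
same pipeline, chosen once as the smallest configuration at which
training demonstrably works on one CPU in minutes:

* dataset-structure checks build the full 9800-pair set at 64×64;
* training smoke runs use 196 pairs (7 per combination) of 64×64 images,
  `minFilters = 8`, mixed loss with $\beta = 300$, batch 8, 10 epochs,
  learning rate $7\times10^{-4}$ (the largest of the configured grid —
  appropriate for the short schedule);
* held-out evaluation uses 10 fresh phantoms with a +6 dB cyst, whose
  sign makes "CNR should increase" directionally unambiguous, with ROIs
  derived automatically from the structure annotations (`autoRois`).

At this scale the trained network behaves as a learned despeckler: on
held-out simulated images it roughly halves (or better) the display-
domain MSE to ground truth and raises mean cyst CNR, and the acceptance
script recomputes those numbers end to end. What desk-scale passing does
*not* show: convergence behaviour of the full 30-epoch schedule,
resolution recovery at the paper-scale PSF-to-image-size ratio, or
performance on real scanner images — the simulator omits attenuation,
depth-dependent blur, nonlinear propagation and scan conversion, so
results on simulated pairs are an upper bound on what transfers to real
tissue.

### The PSF-matching effect and why it is tested at 128 px

Training-PSF / test-PSF mismatch degrades reconstruction of a
matched-PSF test image — this is the reason the pipeline estimates the
PSF before simulating the training set, and the acceptance suite
reproduces it qualitatively: a model trained at PSF (2.0, 2.0) px scores
worse mean validation MSE than a matched (6.2, 2.8) px model on
held-out images simulated at (6.2, 2.8). The comparison deliberately
runs at an image side of 128 px rather than the 64 px of the other
smoke runs: with a 6.2-px PSF, a 64-px image holds only a couple of
hundred independent speckle cells, too few for a briefly trained model
to learn grain-size-specific statistics — at that scale both models act
as generic smoothers and the effect disappears into
training-to-training noise. At 128 px the scale separation between
speckle grain and image content is sufficient and the effect is
reproducible across seeds. Both models use the same pair count, recipe
and seeds; only the training PSF differs.

## Persistence and interfaces

Datasets persist as directories of 32-bit float TIFFs plus a JSON
manifest recording PSF sizes, per-pair seeds, combo labels, split and
normalization (`saveDataset`/`loadDataset`); single images as float TIFF
or 8-bit PNG; models as an RDS checkpoint with a JSON sidecar carrying
both configurations and the training PSF (`saveModel`). Every random
draw in a pipeline run derives from one master seed, and
`runFullPipeline` writes a manifest sufficient to reproduce the run. A
thin command-line wrapper (`inst/scripts/echomap-cli.R`) exposes
`simulate-dataset`, `estimate-psf`, `train`, `despeckle`, `evaluate`,
`compare` and `full-run`.

## Known limitations

* The Gaussian, spatially invariant PSF and the absence of attenuation
  or phase aberration are idealizations; the training-data generator is
  the component to extend for realism.
* The network implementation is single-threaded CPU code built for
  correctness and desk-scale reproducibility, not GPU-scale throughput.
* Printed PSNR values follow Eq.-literal $10\log_{10}(255^2/MSE)$; pairs
  of published MSE/PSNR numbers are not always mutually consistent under
  that identity, so comparisons should fix one of the two.
* The diagonal-joint MI is tiny for images that agree only up to noise;
  its logarithm base (2 here) must match before comparing magnitudes.
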