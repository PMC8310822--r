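---
title: "Simulating and denoising low-dose CT: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and denoising low-dose CT: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldctbench)
```

`ldctbench` benchmarks image-space denoisers for low-dose computed
tomography. It provides the full chain — dose-reduction noise simulation,
classical filters, a residual-learning CNN with a transfer-learning
protocol, and quantitative image-quality evaluation — on synthetic
abdominal phantoms, so every result in the package is reproducible
offline from a single seed. This vignette explains the underlying models,
the parameters that matter, and the design decisions taken where the
methodology left genuine latitude.

## The dose-reduction noise model

CT quantum noise is photon-counting (Poisson) noise, the dominant noise
source under X-ray dose reduction: fewer incident photons mean noisier
reconstructions. The benchmark's dose-equivalence convention assigns
each dose fraction $d$ a noise scale factor $k$ — the multiple of the
normal-dose noise SD $\sigma_0$ that the simulated image carries. The
four named levels 75%, 50%, 10% and 5% use factors 1.3, 2, 10 and 20;
these follow the rule $k = 1/d$ up to the rounding of the first value
(1/0.75 = 1.33 → 1.3). `noise_factor()` returns the printed factors
exactly for the named levels and $k = 1/d$ for any other fraction.

A reconstructed CT image does not contain white noise: the scanner's
modulation transfer function (MTF) shapes the spatial frequency content
of both signal and noise, so the noise power spectrum is proportional to
$\mathrm{MTF}(f)^2$. `simulate_low_dose()` therefore:

1. draws an independent unit-variance noise field — Gaussian by default,
   which is the high-count limit of Poisson counting statistics; an
   exact per-pixel Poisson pseudo-count mode (`noise_model = "poisson"`)
   standardizes `rpois` draws instead;
2. multiplies its 2-D Fourier transform by $\mathrm{MTF}(f_r)$, where
   the radial frequency $f_r$ (cycles/mm) is computed from the physical
   pixel spacing;
3. zeroes the DC coefficient, which makes the field exactly zero-mean;
4. rescales so the empirical SD equals the target exactly; and
5. adds the field to the normal-dose image.

Two calibration conventions exist in the literature and both are
provided. The default (`mode = "total"`) treats $k$ as the *total* noise
of the low-dose image: because the original noise $\sigma_0$ stays in
the image, the added component is $\sigma_0\sqrt{k^2-1}$, so that under
independence the result carries $k\,\sigma_0$ of total noise. The
alternative (`mode = "added_equals_target"`) adds $k\,\sigma_0$ outright.
The package's acceptance checks measure *total* noise by differencing
against the noiseless phantom, so they are valid under either reading;
`total` is the default because the simulated image is described as
*having* $k$ times the original noise, not as receiving it on top.

Because no projection (sinogram) data exist for image-domain simulation,
no attempt is made to model bowtie filtration, scatter, tube-current
modulation or reconstruction-kernel interactions; the model reproduces
exactly two measurable properties — Poisson-scaled magnitude and
MTF-shaped correlation — and nothing else.

### The MTF curve

A measured scanner MTF is rarely published as a table, so the package
ships a smooth Gaussian-shaped stand-in: modulation 1 at zero frequency
falling to 0.05 at the Nyquist frequency of a 0.7 mm grid
(≈ 0.714 cycles/mm), sampled at 30 points
(`inst/extdata/default_mtf.csv`). Any two-column CSV
(frequency cycles/mm, modulation) can be substituted via
`read_mtf_csv()`; every test and acceptance property is agnostic to the
particular curve — they only require that the realized noise spectrum
match whatever curve was configured.

### The baseline noise SD

The scale factors multiply the *noise* SD of the normal-dose image, not
its whole-pixel SD (which is dominated by anatomy). When
`baseline_noise_sd` is not supplied, `estimate_noise_sd()` estimates it
robustly: the median absolute deviation of the image's Laplacian
residual with the Gaussian consistency constant, divided by the
Laplacian's noise gain $\sqrt{20}$. The second-derivative residual
annihilates constant and linear trends, making the estimate insensitive
to smooth anatomy; it is exact for white noise and a mild underestimate
for strongly low-pass (MTF-shaped) noise, which is why the benchmark
pipelines pass the known phantom noise SD explicitly.

### The dose schedule

The transfer corpus uses a 10-step schedule from the original dose down
to 1/100. The intermediate levels are a free choice; the package uses
ten geometrically spaced fractions (`dose_schedule(10, 0.01)`), which
spaces the noise factors evenly on a log scale.

## The synthetic phantom corpus

`abdominal_phantom_spec()` composes an axial abdominal slice from
ellipses — body outline of soft tissue (~40 HU), liver (~60 HU), spleen,
kidneys, aorta, a vertebral body (~400 HU) and a bowel-gas pocket
(−800 HU) on an air background — plus Gaussian texture of 10 HU SD
emulating a routine normal-dose acquisition. A jitter seed perturbs organ
positions, sizes and HU values by a few percent so a corpus of distinct
slices can be generated deterministically.

What the phantom does *not* emulate: streak artifacts, beam hardening,
anatomical texture (vessels, parenchymal heterogeneity), partial-volume
edges, or the reconstruction kernel's resolution loss. Passing tests on
phantoms therefore demonstrate that the pipeline's *mechanics* are
correct — calibration, spectra, optimization, bookkeeping — not that any
denoiser's clinical performance on patient data is established. Ellipse
rasterization uses a pixel-center-inside test (a pixel belongs to the
ellipse iff its center satisfies the ellipse inequality), the simplest
rule with exactly testable geometry.

## Classical baselines

Three image-space filters are implemented exactly as parameterized in
standard practice: a 3×3 median, an isotropic Gaussian with σ = 1 pixel
(kernel truncated at 4σ), and a 5×5 local adaptive Wiener filter,

$$\hat{x} = m + \frac{\max(0, v - \nu)}{\max(v, \nu)}\,(x - m),$$

with local mean $m$ and variance $v$ over the 5×5 window and noise
variance $\nu$ defaulting to the mean of all local variances (the
classical adaptive estimator). All three share a single border policy —
edge replication — so that cross-method comparisons are not confounded
by boundary handling. Each filter is verified against an independent
brute-force sliding-window implementation in the test suite.

## The residual-learning network

The denoising CNN follows the standard residual-learning design: a stack
of `depth` 3×3 convolutions (default 20) with `filters` channels
(default 64), batch normalization between convolution and ReLU in all
middle layers, and a single-channel output head. The network predicts
the *noise residual*; the denoised image is input minus prediction,
which gives the exact identity `denoised + residual = input` (verified
to < 1e-4 HU through the normalization round-trip). The receptive field
is $2\,\mathrm{depth}+1$ pixels (41 for the default).

Implementation notes:

* Convolutions run as per-sample im2col + BLAS GEMM in a small C++
  kernel; activations travel as `(pixels × channels)` matrices so batch
  norm and ReLU need no data rearrangement. Gradients were verified
  against central-difference numeric differentiation (relative error
  < 1e-8 on random configurations).
* Loss is mean squared error between predicted and true residual — the
  standard objective for this architecture.
* Intensities are normalized to [0, 1]: over [−1024, 1024] HU for CT
  (configurable window) and over [0, 255] for the grayscale pretraining
  corpus. Residuals are differences and so scale by the window width
  with no offset.
* Initialization is He (fan-in) scaling, deterministic per seed. The
  Adam optimizer (lr 1e-3, β = 0.9/0.999) and per-epoch reshuffling are
  driven by the training seed, so a training run is a pure function of
  (data, config, seeds) on a fixed BLAS; multi-threaded BLAS may permute
  floating-point summation across *machines*, relaxing cross-machine
  equality to statistical equality, but repeated runs in one environment
  are bit-identical.

### Training protocol

The patch pipeline draws 50×50 patches, 15 per image, at positions
uniform over the valid top-left corners, with augmentation by a random
choice of {0°, 90°} rotation plus an independent random horizontal flip,
applied identically to both members of a noisy/clean pair. Arbitrary
rotation angles were deliberately excluded: they would require
interpolation, which decorrelates the noise residual from its clean
counterpart and breaks the pairing. The validation split (5% by default)
is by *image*, not by patch, so no validation pixel is ever seen in
training.

Pretraining uses a synthetic stand-in corpus: piecewise-smooth grayscale
textures (ramps, soft blobs, hard-edged rectangles) corrupted with white
Gaussian noise of σ = 25 on the 0–255 scale. This mirrors the role of a
natural-image pretraining corpus — learning generic noise removal on
flat regions, edges and gradients — at desk scale; it does not reproduce
any published pretrained weights.

Transfer learning continues training on dose-simulated CT pairs, in two
modes. `all_layers` fine-tunes everything. `final_layer_only` updates
only the last convolution — the output head; the architecture is fully
convolutional, so "the last layer" can only mean this head — and the
contract is *bit-exact*: every other parameter tensor, batch-norm
running statistics included, is identical before and after (frozen
batch-norm layers run with their stored running statistics). Because
nothing below the head changes, the backward pass stops there, which
also makes frozen-mode training substantially cheaper.

## Image-quality evaluation

`mse()` is the plain mean of squared differences. `psnr()` is
$10\log_{10}(\max|x|^2/\mathrm{MSE})$ with the peak taken as the maximum
absolute value of the reference image, implemented as defined; note that
for HU images containing air the −1024 floor often *is* that maximum, so
an explicit `peak` (e.g. a fixed data range) can be supplied when
comparability with intensity-windowed conventions is wanted. Identical
images yield an `NA` sentinel with a warning rather than an infinite
number. `ssim()` evaluates the structural-similarity formula

$$\mathrm{SSIM}(x,y) = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
{(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}$$

in *global* mode by default — one evaluation with whole-image means,
sample variances ($n-1$) and covariance — because the formula is stated
without windowing; the common practice of averaging the local SSIM map
over 11×11 Gaussian-weighted windows (σ = 1.5) is available as
`mode = "windowed"` and is labeled as such in outputs. The constants
default to $C_i = (K_i L)^2$ with $K_1 = 0.01$, $K_2 = 0.03$ and $L$ the
reference image's data range; supplying a fixed `data_range` (or
explicit constants) makes the measure exactly symmetric in its
arguments. Note that global SSIM on a full CT slice is dominated by the
anatomy's variance, so its values sit close to 1 and differences between
methods are numerically small though consistently ordered; the windowed
mode spreads the scale.

Method comparisons use a paired two-tailed t-test on per-image scores
(the natural pairing unit), with $n-1$ degrees of freedom. Degenerate
inputs are handled explicitly: all-zero differences give $p = 1$, and
constant nonzero differences (infinite $t$) give the underflow-safe
minimum p-value rather than an error. No multiple-testing correction is
applied, matching the benchmark's design of reporting raw pairwise
tests. The test suite confirms the p-values are uniform under the null
(Kolmogorov–Smirnov over 500 simulated replicates).

## Orchestration and reproducibility

`run_benchmark()` executes the full factorial design — images × dose
levels × methods — and writes simulated and denoised images, the metric
table (CSV and JSON with a config snapshot), training curves, and a
stage log. A single global seed is fanned out to every stochastic stage
by hashing the stage name (`derive_seed()`), so any stage can be rerun
in isolation and a rerun of the whole benchmark is byte-identical.
Metric CSVs are written with fixed 10-significant-digit formatting to
keep them stable across R versions' default-format changes.

Problem sizes in the shipped configurations are desk scale by design:
the tests and the acceptance script train a depth-5/16-filter network
for 10–30 epochs on ~200–300 patch pairs and evaluate on 128×128
phantoms, which demonstrates every contract (calibration, spectral
shaping, learning improvement, freezing, determinism) in minutes on one
CPU. The full-size architecture (depth 20, 64 filters) is constructed
and validated structurally, and all code paths are size-blind, but
training it to convergence is a GPU-scale undertaking outside the
package's test envelope.

## Known limitations

* The phantom corpus lacks real anatomical texture and reconstruction
  artifacts; learned models transferred to patient data would need
  retraining on real pairs.
* The image-domain noise model cannot produce streaks or locally
  varying noise (no projection data); its fidelity is limited to
  magnitude and second-order spectral statistics.
* Global SSIM compresses differences near 1 on full slices (see above).
* DICOM support is a minimal single-frame little-endian reader
  (explicit or implicit VR, uncompressed 16-bit) sufficient for CT
  slices; multi-frame, compressed transfer syntaxes and DICOM writing
  are out of scope.
* The PSNR peak convention (max |reference|) follows the stated
  definition; comparisons with literature using a fixed data range
  require the explicit `peak` argument.
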