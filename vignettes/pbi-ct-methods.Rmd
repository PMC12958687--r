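---
title: "Propagation-based phase-contrast CT on synthetic lung data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagation-based phase-contrast CT on synthetic lung data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbict)
```

## The imaging problem

Propagation-based imaging (PBI) exploits free-space propagation between a
specimen and the detector: phase gradients imprinted on a spatially
coherent X-ray beam turn into measurable intensity fringes. For lung
tissue the effect is dramatic — the air/tissue interfaces of the
parenchyma act as millions of tiny phase objects — which is why PBI-CT
resolves peripheral airways, vessels and lobular septa far beyond
clinical multislice CT (MSCT). `pbict` implements the complete
computational chain of such a study on purely synthetic data: a digital
lung-like phantom, a coherent-imaging forward model of a synchrotron
setup with photon-counting detectors, detector-domain pre-processing,
self-supervised sinogram denoising, single-distance phase retrieval with
filtered back projection, and the quantitative image-quality metrics used
to compare detectors and dose settings.

## Geometry and dose model

The setup is a bending-magnet beam monochromatized to 40 keV (0.04 keV
bandwidth, 3 mrad divergence), a specimen about `z_ss = 23` m from the
source, and a photon-counting detector `z_sd = 10.25` m (55 um pixels) or
`z_sd = 10.70` m (100 um pixels) downstream. Two consequences of this
cone-like geometry drive everything else:

* **Effective pixel size.** The detector pixel demagnified to the sample
  plane is `p_nom * z_ss / (z_ss + z_sd)`: 38.05 um for the fine-pixel
  detector. The coarse-pixel detector yields 68.25 um by the same
  formula; published summaries of the setup quote 67 um, presumably from
  slightly different distance bookkeeping — the package always exposes
  the full-precision value and leaves rounding to the caller.
* **Source-spot blur.** An incoherent source of extent `s` projects a
  penumbra of width `s * z_sd / z_ss` onto the detector. Conversely, a
  blur measured on an edge projection multiplied by the distance ratio
  `z_ss / z_sd = 2.24` estimates the source spot; with measured blurs of
  230 um and 77 um this gives the ~515 x 172 um anisotropic spot that
  limits the achievable resolution.

Dose accounting is deliberately pure bookkeeping: this kind of experiment reports an
entrance dose and an "exposed tissue" dose, related by a factor 1/2 for
off-center 360-degree scans (most tissue is in the beam for only half the
rotation) and scaling linearly with the fraction of projections used.
With a 23 mGy entrance exposure this reproduces 11.5 mGy for the full
projection set and 5.75 mGy for half of it. No depth-dose or
beam-hardening physics is modeled, matching the level of detail such
dose reporting itself uses.

## The phantom generator: what it emulates, and what it does not

`build_lung_phantom()` produces congruent `delta` (refractive-index
decrement), `beta` (absorption index) and integer label maps. The
in-plane structure emulates the anatomy such scans image: an elliptical
pleural outline filled with low-density parenchyma, polygonal secondary
lobules separated by 1-2 voxel septa (a Voronoi tessellation of random
seeds), a branching air-filled airway tree with soft-tissue walls (five
generations at the default grid), a vessel tree, and optionally a few
"ground-glass" lobules whose parenchyma density is raised while the
air-filled airway branches crossing them are retained — the pattern of
partial alveolar collapse.

Optical constants are soft tissue at 40 keV (delta = 1.4e-7 for unit
density) scaled by representative densities (0.25 for inflated
parenchyma, 0.6 for dense lobules, ~1 for walls, vessels and septa), with
a single delta/beta ratio of 2000 for every material. A single global
ratio is what single-distance TIE-Hom retrieval assumes, so the phantom
is exactly "homogeneous" in the retrieval sense; real lungs only
approximately satisfy this.

Two deliberate simplifications: the structure is extruded along the
axial direction (the vertical field of view of the real scans is only
2-2.5 mm, so in-plane structure dominates), and alveoli (~100 um) are
not modeled individually — at a 38 um effective pixel they sit at the
resolution limit and would dominate runtime. Passing tests on this
phantom therefore demonstrates correctness of the *pipeline*, not
fidelity to every microstructural property of real lungs.

## Forward model

`project_thickness()` computes parallel-beam line integrals of the delta
and beta maps on the effective-pixel grid; with 3 mrad divergence at 23 m
and a thin vertical field of view, cone-beam effects are sub-pixel, so a
parallel model with demagnified pixels matches how such setups treat their
own geometry. `fresnel_propagate()` forms the exit wave
`exp(-(2*pi/lambda)*B) * exp(-i*(2*pi/lambda)*A)` from the beta and delta
path integrals and applies a single-FFT Fresnel transfer function over
the effective distance `z_eff = z_sd*z_ss/(z_ss+z_sd)` (the Fresnel
scaling theorem pairs this with the demagnified pixel). Fields are
edge-padded to powers of two; the unit-modulus kernel conserves energy
exactly, which the tests assert. The first Fresnel fringe width
`sqrt(lambda*z_eff)` is ~15 um — below the pixel — so simulations that
need fringe-accurate intensities (the cylinder-retrieval check) sample
the wave at 8x finer pitch and integrate over detector pixels;
single-pitch simulation slightly aliases the fringes but is adequate for
everything else.

Source blur is applied to the propagated intensity as an anisotropic
Gaussian with detector-plane FWHM `spot * z_sd / z_ss` per axis — the
standard partially coherent approximation of convolving with the
projected source. The detector stage draws Poisson counts at
`intensity * mean_flat_counts`, then imposes the defect structure: the
fine-pixel ("lambda"-like) layout has a central inter-panel gap, single
rows/columns of enlarged pixels at module contact zones (pooled 3x3
neighborhood counts at double area) and sparse random dead pixels; the
coarse-pixel ("hydra"-like) detector has a 100% filling rate and an empty
mask. The exact vendor layout is not public; the parameterized layout
reproduces its qualitative classes. All randomness flows through one
seed recorded in the stack metadata.

## Pre-processing

Flat-field correction divides by the mean flat (dark-subtracted when
darks exist) and promotes zero-flat pixels into the defect mask rather
than dividing by them. Defect inpainting solves the Laplace equation
over the masked pixels by Jacobi iteration (a deterministic diffusion
fill — reproducible bit for bit, unlike stochastic texture synthesis),
with a row-wise linear-interpolation fallback and a warning for masked
column bands wider than `max_gap`.

Off-center 360-degree scans are converted to extended 180-degree
sinograms by mirroring each projection's conjugate half a turn away about
the rotation axis and fusing the two on their overlap with a cosine
feather (default 20 px wide) that suppresses seam artifacts. When twice
the axis offset is integral the mirrored samples land exactly on the
direct grid and no interpolation happens at all; the tests exploit this
to show the extension equals a directly simulated wide-detector scan to
numerical precision. The axis offset itself can be estimated by
cross-correlating projections with their mirrored conjugates (the peak
sits at twice the offset; parabolic subpixel refinement, median over
angle pairs). A consistency check compares the angle-averaged lateral
profiles of the two halves against the noise level estimated from
angle-to-angle differences; it reports a chi-square-like mismatch score
because at very low flat counts the overlap band carries too little
contrast for plain correlation to be meaningful.

## Self-supervised sinogram denoising

The denoiser follows the Noise2Noise idea: two images of the same signal
with independent noise can supervise each other, because the MSE-optimal
predictor converges to the conditional mean. Here the two realizations
are the even- and odd-indexed projections of one sinogram — they
interleave exactly back to the parent, and at 0.5-degree angular steps
the underlying signal differs negligibly between them while the Poisson
noise is independent.

The network is a small 4-level encoder-decoder: 3x3 convolutions, 2x2
max pooling, nearest-neighbor upsampling, skip concatenations, and a
residual output head initialized at zero so the untrained network is the
identity. Convolutions use clamp-to-edge padding so a constant sinogram
maps to a constant. With no deep-learning framework among the package's
dependencies the network — forward pass, backpropagation and Adam — is
implemented directly in vectorized R (im2col convolutions as matrix
products); at the 8-to-32-channel widths used here this trains a model in
seconds on one CPU, which also keeps the test suite self-contained.
Training samples random 64x64 patches (divisible by 2^3 for the three
pooling stages) in both pairing directions, masks defective detector
columns out of the loss, holds out whole sinograms (80/20 split) for
validation, and early-stops when validation MSE stagnates. Separate
models are intended per detector configuration, mirroring the usual
protocol, and denoising is applied in sinogram space before inpainting
and phase retrieval.

The pipeline enforces the dose-parity comparison design: a denoised
full-projection reconstruction is compared against a *half*-projection
non-denoised reconstruction (5.75 vs 11.5 mGy bookkeeping carried in the
sinogram metadata), never against the full-projection raw one.

## Retrieval, reconstruction, stitching

Single-distance TIE-Hom retrieval applies the homogeneous-object filter
`1 / (1 + pi*lambda*z_eff*(delta/beta)*|f|^2)` to the flat-normalized
intensity in frequency space and takes `-log`, yielding an image
proportional to projected thickness times the attenuation coefficient.
The pipeline fixes delta/beta = 2000; wavelength, effective distance and
pixel size come from the geometry. Inputs are edge-padded to powers of
two; non-positive filtered intensities are clamped at 1e-8 and counted.
For sinograms the filter acts along the detector axis of each projection
row, consistent with slice-wise simulation.

`fbp_reconstruct()` is classical filtered back projection: the discrete
Ram-Lak convolver (optionally Shepp-Logan apodized; the default is the
plain ramp, matching a "classical" reconstruction) applied by FFT,
linear-interpolation backprojection onto a grid whose side equals the
sinogram width, and scaling by the pixel size so reconstructed values are
attenuation per meter. The reconstruction software used in the original
processing chain does not document its padding/apodization, so bit-level
agreement is not claimed — the tests instead verify against analytic
oracles (a disk reconstructs to its known attenuation within 2% at 360
angles).

`stitch_vertical()` concatenates axial slabs, estimating unknown overlaps
by cross-correlating axial mean-intensity profiles (preferring the
longest strongly correlating overlap) and fusing overlapping slices with
a linear feather.

## Image-quality metrics

* **CNR** is exactly `|S1 - S2| / sqrt(0.5*(sd1^2 + sd2^2))` over two
  disjoint regions of at least 25 px, with a triplicate helper mirroring
  the three-measurement protocol. Region pairs in the pipeline QA put
  each dense-lobule patch next to its nearest parenchyma patch, because
  the definition assumes *adjacent* homogeneous regions (this minimizes
  the influence of low-frequency shading).
* **Edge FWHM** uses the difference-coefficient definition: the absolute
  first derivative of a profile, min-max normalized, with the width
  between the half-maximum crossings. Two numerical refinements give it
  subpixel accuracy: the derivative samples are oversampled 8x by
  band-limited FFT interpolation before locating the crossings, and the
  1-px difference kernel's box contribution (1/12 px^2 of variance) is
  removed in quadrature. A Gaussian edge of scale sigma then reports
  `2*sqrt(2*log(2))*sigma` to well within 2% for sigma >= 1 px; a
  single-sample derivative spike reports the conventional 1 px floor.
* **measure_edge_blur()** extracts many profiles across a straight edge,
  aligns them by integer shift on a noise-robust subpixel edge-position
  estimate (derivative-peak-local centroid), averages, and corrects both
  the difference-kernel box and the residual alignment jitter in
  quadrature. It feeds `source_spot_from_blur()`.
* **Radial power spectra** zero the DC bin, bin the 2-D power radially in
  cycles/mm (bin width 1/side-length, so differently sampled regions of
  equal physical size share an axis) and normalize total power to 1.
* **simulate_msct_resolution()** degrades a volume to clinical sampling
  (0.76 mm pixel spacing, 0.625 mm slices by default) by exact
  area-weighted box averaging — the box average is itself the anti-alias
  filter, and non-integer factors are handled by cumulative-sum
  integration.

In the pipeline QA the edge-sharpness triplet is measured from the
air-filled lumen of the main bronchus to its wall — the generator places
that segment on the equator row, so profiles at several column groups
along the tube are aligned by construction, and the air/wall contrast is
the strongest edge the phantom offers. This mirrors the bronchial-wall
protocol of quantitative lung CT comparisons and keeps the estimator
stable at the low photon counts where denoising matters.

## Study conditions of the synthetic comparisons

The packaged experiment (`run_experiment()`) uses, per seed: a 160^2
phantom slice extruded to 3 detector rows (the extra rows provide three
sinogram pairs so the denoiser has a held-out validation sinogram), an
off-center 360-degree scan with 360 projections, mean flat counts 200
(within the low-count regime of the fine-pixel detector settings), the
fine-pixel defect layout, Fresnel propagation and source blur on, and
delta/beta = 2000 retrieval. These sizes keep a full experiment around a
minute on one CPU while preserving every qualitative feature of the
full-scale protocol (1554-column detectors, 1800-3600 projections); the
same code runs at full scale unchanged. The MSCT-resolution
demonstration models the parenchymal background as a correlated Gaussian
texture (1.5 mm correlation length — the scale of lobular structure)
plus fine white noise, with a one-voxel septum at 8x the texture SD:
lobular-scale texture is exactly what survives downsampling and hides
the diluted septum, which is the mechanism by which MSCT loses such
features.

## Numerical choices and degenerate inputs

* Angles are degrees, counter-clockwise, stored explicitly in every
  sinogram; parity splits index from 0.
* Fourier padding is always to the next power of two with edge
  replication; the Fresnel kernel warns and enlarges the field if the
  anti-alias bound `z <= N*px^2/lambda` is violated.
* `cnr` returns 0 for two identical constant regions and flags +Inf when
  the means differ at zero variance; constant regions give a degenerate,
  all-zero radial spectrum rather than NaNs.
* Reconstruction values are 1/m; display layers may rescale, the core
  never does.
* All stochastic stages (phantom, Poisson draws, training, pairing,
  scoring pairs) consume explicit seeds and restore the caller's RNG
  state.

## Known limitations

Polychromaticity, scatter, detector charge sharing and phantom motion
are not modeled. The dose model is bookkeeping, not transport. The
denoiser is deliberately small; it demonstrates the Noise2Noise
mechanism and its CNR/sharpness trade-off but will not match a
GPU-trained production model. The off-center extension assumes a rigid
axis (no wobble), and stitching assumes congruent lateral grids.
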