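---
title: "Burst-mode 4D OCM processing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst-mode 4D OCM processing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the science behind `speckle4d`: what each stage of the
pipeline computes, why, which parameters matter, and where design choices were
genuinely open. It also describes exactly what the synthetic phantom does and
does not emulate, so that the reader can judge what a passing validation run
demonstrates about real data.

## The measurement problem

Optical coherence microscopy (OCM) images a multicellular spheroid embedded in
a collagen-I gel, label-free, for 48 h at 40-min intervals. Each time-point is
a *burst*: N = 8 reduced-field volumes acquired within ~2 min. Because the
inter-acquisition interval (~12-15 s) is long compared with intracellular
motion but short compared with collagen remodelling, the coherent speckle
pattern of live cells decorrelates between burst frames while collagen speckle
stays frozen. This temporal contrast is the only label available, and the
entire pipeline is built on it.

## Burst statistics (cell and collagen channels)

For burst frames $S_i(x,y,z,t)$, $i = 1 \dots N$, the pipeline computes the
per-voxel *mean projection*

$$\bar S = \frac{1}{N}\sum_{i=1}^N |S_i|$$

and the *standard-deviation projection*

$$S_\sigma = \sqrt{\frac{1}{N-1}\sum_{i=1}^N \left(|S_i| - \bar S\right)^2},$$

with the sample (1/(N-1)) normalisation. $S_\sigma$ is bright where speckle
decorrelates (cells) and dark where it is static (collagen): it is the raw
'cell' channel. $\bar S$ averages speckle and is the basis of the 'collagen'
channel. Both operate on *linear amplitude*; decibel scaling is display-only.
Numerically, `std_projection()` accumulates deviations from the first frame,
which is cancellation-safe and returns exactly zero wherever all frames agree.

Both channels are then down-sampled 768:400 laterally and to isotropy axially
(`downsample_isotropic()`), which yields the (1.88 um)^3 / (2.34 um)^3 voxels
of the two culture settings and doubles as smoothing. The axial factor is not
specified independently anywhere; isotropy at the new lateral pitch is the
rule adopted here because it is the only rule consistent with the published
cubic voxel sizes. The resampler prefilters with a Gaussian of
$\sigma = 0.5\sqrt{f^2 - 1}$ voxels per axis (reduction factor $f$) and
interpolates with a Catmull-Rom cubic.

The 'cell' channel carries a depth-dependent additive background (incoherent
stray signal and sensitivity roll-off). It is estimated as the per-depth
*median* over a peripheral frame of the lateral FOV — the outer 15% on each
side by default, a region that excludes the spheroid and the glass — and
subtracted, clamped at zero. The clamp is a choice the source protocol leaves
open; amplitudes are non-negative and a clamp keeps negative noise excursions
out of the Otsu histogram.

## Segmentation

The cell channel is median-filtered (5x5x5 voxels, reflecting borders) and
thresholded by Otsu's method on a 256-bin histogram spanning [0, max]. Two
conventions required a decision:

* **Tied histogram bins.** With well-separated classes the between-class
  variance is flat across the empty gap; the threshold is the mean of the
  maximising bin edges (the convention of the common implementations), not
  the first one.
* **Per-volume thresholding.** Each time-point is thresholded independently;
  nothing in the protocol suggests a series-global threshold, and a global
  one would couple time-points through slow drifts in illumination.

Preliminary masks are cleaned by *4D region growing*: at t = 0 only the
largest 26-connected component (the spheroid body) survives; at each later
time-point a component survives iff it shares at least one voxel with the
previous cleaned mask, which then seeds the next step. The overlap rule is
applied literally — no dilation — so a cell that detaches and moves beyond
its own footprint within one 40-min interval is lost; that is a documented
property of the rule, not a defect of the implementation (a dilation radius
is exposed in the configuration for sensitivity studies). 26-connectivity is
used because protrusions are thin and often diagonal; 6-connectivity
fragments them. Ties for the largest component go to the component whose
first voxel comes earliest in column-major scan order — arbitrary but fixed
and tested.

The 'collagen' channel is the down-sampled mean projection with cleaned-mask
voxels set to zero, so collagen x mask = 0 holds exactly, by construction.

## Drift correction

Lateral stage drift is estimated per time-point from four peripheral strips
(W/E/N/S; by default the outer 25% of each lateral edge, leaving the central
50% x 50% block to the spheroid and glass). Each strip of the mean projection
is cross-correlated against the same strip of the *previous* time-point; the
peak is refined to 0.01-voxel precision by local Fourier up-sampling
(matrix-multiply DFT, coarse-to-fine). Two de-biasing steps precede the
correlation, both of which measurably matter at the 0.1-voxel level: the
per-depth-plane mean is subtracted (a static additive depth background does
not translate with the sample and drags the peak toward zero lag), and a
4-voxel border of the moving strip is zeroed so that every retained voxel has
a matching partner in the reference for lags up to that margin — without
this, the finite window's overlap envelope biases each step a few hundredths
of a voxel toward zero, which accumulates linearly over the series through
the cumulative summation. The step drift is the component-wise
median of the four strips (with four values, the mean of the two central
ones), which tolerates one corrupted strip outright; the cumulative drift is
the running sum from t = 0. Step-wise estimation rather than direct
t-versus-0 correlation matters because collagen texture decorrelates slowly
over the series.

Correction translates every volume by the negative cumulative shift through a
spectral phase ramp — an exact sub-pixel translation for band-limited data,
with no resampling blur — and zero-fills the circularly wrapped border
columns. Only (x, y) are corrected; the axial component of each strip
estimate is computed and reported for diagnostics, but axial drift is
handled upstream of this pipeline (during image reconstruction) and is out of
scope here.

## Deformation tracking

Collagen displacement is tracked with Thirion's demons algorithm: the t = 0
collagen channel (moving image) is registered onto the collagen channel of
each time-point (fixed image) up to a 24-h horizon. Per iteration the classic
optical-flow-like force

$$\delta u = \frac{(M_w - F)\,\nabla}{|\nabla|^2 + (M_w - F)^2}$$

is subtracted from the accumulated field, which is then smoothed with a
Gaussian of sigma = 2 voxels (diffusion-like regularisation), inside a
3-level coarse-to-fine pyramid with 100 iterations per level — the published
parameter set, with "accumulated field smoothing" interpreted in voxels of
the processing grid at each level. Implementation choices:

* **Gradient.** The default force uses the mean of the fixed-image gradient
  and the gradient of the warped moving image ("symmetric" demons); the pure
  fixed-gradient variant is available (`symmetric = FALSE`) and is the one
  used when cross-checking against a reference implementation that defines
  only that variant. On the phantoms the two agree to well under half a
  voxel.
* **Intensity normalisation.** Both images are divided by their joint
  maximum before registration, because the demons denominator mixes gradient
  and intensity units; this makes the result invariant under global
  amplitude rescaling (verified by test).
* **No diffeomorphic constraint.** The published processing used the
  non-diffeomorphic variant; `jacobian_report()` quantifies folding if a
  user needs the diagnostic.
* **Sign convention.** The returned field is the pull-back field: resampling
  the t = 0 image at $x + u(x)$ reproduces the time-t image. The physical
  matrix displacement is $-u$ at the corresponding point, to first order.
  The synthetic ground truth is stored in the same convention, so
  registration output and truth are directly comparable.

The tracking horizon (default 1440 min) exists because elastic registration
assumes deformations stay small and topology-preserving; once invasion
substantially degrades and reshapes the matrix, those assumptions fail and
later time-points are skipped with a logged message rather than reported
with false confidence.

The *displacement noise floor* is estimated by registering pairs of
nominally static volumes and taking the median over pairs of the median
displacement magnitude over the grid interior (one smoothing length of
border excluded). The exact definition used in the source protocol is not
public; median-of-medians is this package's definition, chosen to be robust
and scale-free, and is flagged as an assumption. On the default phantom it
comes out near 0.5-1% of the voxel pitch — the same sub-voxel order as the
34-41 nm floors reported for the real instrument at 1.88-2.34 um pitch.

## The synthetic phantom

`generate_timelapse()` produces the study conditions every validation number
in this package is computed under:

* **Collagen**: a circular complex Gaussian scatterer field convolved with a
  Gaussian PSF (sigma 1.5 um lateral, 2.4 um axial — the system's stated
  resolutions), magnitude taken. The amplitude is exactly Rayleigh (fully
  developed speckle, contrast 0.5227); the PSF convolution uses periodic
  boundaries so the field is stationary to the edge.
* **Cells**: inside a spherical mask (radius 55 um, four cylindrical
  protrusions, optional linear growth) the speckle is a complex AR(1)
  process across burst frames with coefficient sqrt(rho), making the
  consecutive-frame *amplitude* correlation approximately rho. The default
  rho = 0.2 is a free parameter of the phantom, not a biological claim — no
  quantitative decorrelation statistics exist for the ~12-15 s inter-frame
  interval. Cell amplitude is 1.5x the mean collagen amplitude.
* **Contraction**: the collagen is warped by an analytic radial field,
  $|u|(r) = A (R/r)^p$ outside the inclusion (linear inside), curl-free
  outside R, ramped linearly in time to A at the last time-point
  (default A = 4 um, p = 2 — the far-field decay of a point-like
  contraction in an incompressible medium). The stored ground truth is the
  exact pull-back field used to synthesise each frame.
* **Drift**: a cumulative per-step lateral translation applied by Fourier
  phase ramp (default zero; validation scenarios use 1-2 voxels/step).
* **Background and noise**: an additive depth profile
  $B(z) = 0.25\,e^{-3z/n_z}$ on the unit-mean amplitude scale, plus additive
  Gaussian amplitude noise (sigma 0.05), clamped at zero.
* **Grid**: 128 x 128 x 96 voxels at 1.88 um — the post-down-sampling pitch
  of the monoculture setting, at a desk-scale FOV so the full pipeline runs
  in minutes. Module-level tests use 48-64 voxel grids; the vignette-scale
  numbers quoted anywhere in the package are computed at the sizes stated in
  the tests and acceptance script that produce them.

What the phantom does *not* emulate — and hence what passing tests do not
show about real data: coherent image formation through a real objective
(defocus, aberrations, coherence-gate curvature), multiple scattering and
attenuation with depth, collagen fibre micro-architecture and its anisotropic
texture, cell migration and matrix degradation mechanics, and axial drift.
Validation numbers demonstrate that the *algorithms* recover known answers
under realistic speckle statistics and SNR, not that the biological protocol
itself is reproduced.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based in coordinate formulas; a voxel's physical
  coordinate is its centre; z increases with depth.
* Resampling aligns voxel centres so physical extent is conserved;
  out-of-domain samples in warps are zeroed and flagged.
* Median filter and Gaussian smoothing reflect at borders (periodic only for
  phantom synthesis, where stationarity matters).
* Constant volumes are rejected by Otsu and by registration (no separable
  classes / no gradient information); N = 1 bursts are rejected by the
  std projection (the 1/(N-1) normalisation is undefined).
* A failed drift strip is dropped and the median taken over the remainder;
  fewer than two surviving strips is an error, not a silent zero.
* All randomness is seed-derived; identical configuration and seed give
  bit-identical pipeline products (hash-verified in the tests).

## Known limitations

Registration accuracy assertions deliberately exclude voxels within one
smoothing length of the cell boundary and of the FOV border: the demons
field is unconstrained where the collagen channel is zeroed (cell interior,
zero-filled drift margins), and no claim is made there. Displacement
estimates very close to the cell surface are therefore qualitative. The 4D
region-growing rule can lose fast-detaching cells, as discussed above. The
noise-floor definition is package-specific. HDF5 I/O is not provided; the
canonical lossless container is RDS, with a multi-page TIFF + JSON sidecar
for interoperability (32-bit fixed-point, exact to ~2e-10 of each item's
amplitude range).
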