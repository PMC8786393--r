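---
title: "Volumetric image reconstruction of fNIRS data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric image reconstruction of fNIRS data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsdot)
```

Functional near-infrared spectroscopy (fNIRS) measures cortical hemoglobin
changes through source–detector pairs ("channels") on the scalp. Channel-space
analyses inherit the spatial uncertainty of cap placement and head shape;
diffuse optical tomography (DOT) instead reconstructs the measurements into a
voxel volume using a photon-transport sensitivity model as the spatial prior.
`fnirsdot` implements the full chain: digitization cleaning, channel
preprocessing, sensitivity-matrix vectorization, regularized inversion,
spectroscopic conversion to hemoglobin, sphere-based verification against the
channel data, and a voxelwise GLM — together with seeded synthetic generators
for every input, so the pipeline is exercisable and testable without any real
recording.

## Digitization cleaning

A digitization is an ordered list of 3D stylus positions: head landmarks,
then sources, then detectors, in centimeters. Stylus slips displace single
points far from the head; the goal of cleaning is to remove exactly that
error while preserving true between-participant variation in cap placement.

Rigid alignment uses the Kabsch algorithm: the proper rotation (SVD-based,
reflections suppressed by sign-correcting the smallest singular vector)
and translation minimizing the RMSD between corresponded points.
Correspondence is positional — cap layouts are fixed per cap design — so no
point-matching search is performed, and alignment is rigid only because
templates are built per cap size.

A **template** per cap size is built by aligning every cap to every other;
a pair "matches" when no aligned point is farther than a threshold (10 cm
works well for whole-head caps) from its counterpart. The cap with the most
matches anchors the template, which is the pointwise mean over the anchor and
its matches. Ties are broken by the lowest mean distance to matches, then by
cap id, making the construction order-invariant.

Three correction methods are provided. `threestep_alignment()` tests points
against the template at three user thresholds (default 12, 10, 7 cm),
re-aligning on the retained points after each pass; points dropped anywhere
are finally replaced with the template's coordinates in the aligned frame.
`iterative_alignment()` automates the schedule, starting at 20 cm and
shrinking by 1 cm per pass until a replacement budget is hit or all retained
points are within 0.5 cm. `headwise_alignment()` replaces whole caps whose
mean point distance exceeds a threshold. Threshold comparisons are strict
(`>` means replace); the choice is documented here because the convention is
not standardized.

One subtlety matters when constructing test cases: each pass aligns on the
currently retained points *including* any not-yet-dropped outlier, so a point
placed k cm from the template sits somewhat closer after alignment (the
least-squares fit partially chases it). Pass thresholds act on the
post-alignment distances.

Corrected caps export as `digpts.txt` (one `label: x y z` line per point,
millimeters), the dialect consumed by common fNIRS anatomy tools.

## The sensitivity model

Photon-transport simulations yield one sensitivity volume per measurement
(channel x wavelength). `vectorize_sensitivity()` flattens these into a
matrix `A` (measurements x voxels), keeping only voxels whose sensitivity
exceeds a fraction (default 0.01, strict `>`) of the global maximum over all
volumes for at least one measurement. The retained-voxel index `good_vox`
(column-major over x, y, z; 1-based everywhere, including exports) maps
columns back to the volume; on the synthetic phantom this shrinks the model
about 7-fold, consistent with the 5–10x savings such thresholding typically
gives. `embed_to_volume()` and `restrict_to_good_vox()` are exact mutual
inverses on the retained set.

## Reconstruction

The inverse problem is penalized least squares,
$\min_x \|y - A x\|_2^2 + \lambda_1 \|L x\|_2^2$, with the spatially variant
penalty $\mathrm{diag}(L) = \sqrt{\mathrm{diag}(A^T A) + \lambda_2}$.
Because superficial voxels are far more sensitive than deep ones, an
unweighted minimum-norm solution reconstructs too superficially; weighting
each voxel's penalty by its aggregate sensitivity counteracts that bias, and
$\lambda_2$ floors the penalty so noise is not amplified into barely-sensed
voxels. Increasing $\lambda_2$ therefore *reduces* the depth boost (it is
maximal at $\lambda_2 = 0$), while any spatially variant `L` boosts depth
relative to `L = I`; both facts are asserted in the test suite. With
$\tilde A = A L^{-1}$ the operator is evaluated in the measurement-space or
voxel-space form — algebraically identical by the push-through identity —
choosing whichever matrix is smaller to invert. Defaults
$\lambda_1 = 0.01$, $\lambda_2 = 0.1$ work across the geometries the
generators produce. Inversion is per wavelength. The printed definition of
`L` in the source literature is ambiguous about the exponent; the
square-root reading adopted here matches the spatially-variant-regularization
literature and is isolated in one function for revision.

Reconstructed images are smoothed with a separable 3D Gaussian (FWHM 3–10 mm
recommended; kernels are normalized to unit mass, so total signal is
conserved up to boundary loss). Since smoothing is linear,
`reconstruct_recording()` folds it into the operator columns — exactly
equivalent to smoothing every frame, at a fraction of the cost.

Two-wavelength absorption changes convert to hemoglobin by solving the 2x2
extinction system per voxel and frame; `HbT = HbO2 + HbR` by definition. The
built-in extinction table covers 690/760/830/850 nm in base-e
mm^-1 per uM units, converted from the standard molar compilation, and is
user-overridable.

## Channel preprocessing

The canonical order is prune → optical density → (motion hook) → trigger
rejection → band-pass → global signal regression → down-sample.

* **Pruning** flags channels whose mean intensity in dB
  (`20 log10(mean I / reference)`) leaves the 80–130 dB window.
* **Optical density** is `-ln(I / mean(I))` per channel (natural log,
  temporal-mean baseline; swap in log10 upstream if preferred).
* **Motion correction is a hook, not an implementation**: published
  channel-space algorithms detect artifacts; `reject_triggers()` consumes
  their intervals and removes any trigger whose `[-1, +18]` s window
  (endpoints inclusive) intersects an artifact.
* **Band-pass** is a zero-phase third-order Butterworth pair at 0.016 and
  0.5 Hz. At cutoffs this far below Nyquist, plain forward–backward filtering
  leaves minute-scale edge transients, so the data are odd-reflection padded
  first.
* **Global signal regression (GSR)** removes, per wavelength, each channel's
  least-squares projection (with intercept) onto the mean over good channels —
  a surrogate for systemic physiology. Residuals are orthogonal to the global
  signal by construction. The global signals are retained on the recording
  for downstream use.
* **Down-sampling** (default 25 Hz) is Fourier-domain resampling (spectrum
  truncation), chosen over polyphase filtering for its flat pass-band;
  duration is preserved to within one sample and paradigm times, in seconds,
  are untouched.

## GLM

`gamma_hrf()` is the SPM-style double gamma (difference of gamma densities;
defaults: response delay 4 s, undershoot delay 15 s, dispersions 1, ratio 6,
onset 0, 16 s kernel), normalized to unit peak — normalization is a
convention, documented because betas scale inversely with it. The mode of the
response component sits at delay minus dispersion (3 s). `build_design()`
convolves per-condition event trains (impulses or boxcars, e.g. the 4.5 s
window of a working-memory trial, or a 10 s event extent) with the kernel in
the time domain (exact zeros outside the support); a condition→regressor map
collapses conditions onto shared regressors when the analysis calls for it.
`fit_glm()` is voxelwise OLS with residual variance; rank-deficient designs
error with the offending columns named. `weighted_average_betas()` combines
runs per condition weighted by event counts, flagging conditions with no
events anywhere.

Two practical rules are baked into the pipeline's GLM stage, both discovered
by exercising the synthetic fixture and both general:

1. **Regressors must traverse the data's operators.** The design is built and
   band-pass filtered at the acquisition rate, then pushed through the same
   Fourier resampler as the data (`filter_design()`, `resample_design()`).
   Building the design directly at the reconstruction rate leaves half-sample
   event-timing mismatches that bias betas of temporally overlapping
   regressors by several percent.
2. **The recorded global signals are not valid GLM nuisance regressors when
   all conditions share one paradigm.** Each wavelength's global mean is a
   mixture of the same two time courses (systemic physiology and the common
   task response), so the pair of global signals spans the task subspace and
   including both drives the task betas to zero. With uniform physiological
   coupling GSR already removes the physiology exactly; its residual cost is
   a uniform shift of the spatial pattern (each channel loses the
   array-mean response), which localization must tolerate. `add_nuisance()`
   remains available for designs where the assumption fails.

## Localization on regularized maps

The spatially variant inverse deliberately flattens amplitude across the
sensitive region, so a reconstructed point source appears as a plateau
roughly 10 mm across at these array densities, with low-amplitude ripple
lobes elsewhere (partly the GSR pattern shift). A raw argmax on such a map is
unstable; `activation_centroid()` instead thresholds at half the (cortex-
masked) maximum, groups suprathreshold voxels into face-connected (NN1)
clusters, and returns the center of mass of the cluster with the largest
integrated value. On the synthetic fixture this localizes the injected focus
to within ~4 mm across seeds, versus up to ~12 mm for an argmax.

## Verification against channel data

Following standard practice, a sphere (2 cm diameter) is centered at each
channel's sensitivity maximum *restricted to cortex* (gray matter by default;
the restriction keeps the center out of scalp and skull). The mean
reconstructed HbO2/HbR series over the sphere is correlated with the
channel's own chromophore series (its two-wavelength OD converted through the
same extinction table, so units differ only by a pathlength scale that
correlation ignores). Agreement above r = 0.25 counts as a pass; argmax ties
break to the first voxel in linear order.

## The synthetic phantom and what it does (not) show

`generate_phantom_head()` builds a concentric-layer spherical head (white
22 mm, gray 28 mm, CSF 30 mm, scalp/skull 36 mm outer radii; 40^3 voxels at
2 mm), `probe_layout()` places 8 source–detector pairs on the scalp (~25 mm
separation), and `generate_sensitivity()` gives each measurement a Gaussian
"banana" — the product of distance-decay kernels from source and detector
(10 mm scale), tissue-masked and peak-normalized. This is a geometric
surrogate for photon transport: non-negative, channel-localized, and
overlapping, which is everything the downstream linear algebra uses. It has
no wavelength dependence by default (a decay-dilation knob exists) and no
realistic optical properties.

`generate_channel_data()` forward-simulates the whole chain: a Gaussian
activation blob (4 mm SD) at a chosen voxel, per-condition peak amplitudes in
uM (defaults in the fixture: HbO2 +1.0/+0.5 uM and HbR −0.3/−0.15 uM for a
2:1 two-condition design; 10 events, 11 s apart — spacing chosen so task
harmonics avoid the 0.1 Hz physiology line), extinction-forward to
absorption, `y = A x` to optical density, plus a shared 0.1 Hz sinusoid
(0.02 OD; systemic oscillations exceed evoked responses in real data) and
white noise (2e-4 OD per 50 Hz sample, a good research-grade system), then
exponentiation to intensities around 100 dB baselines. All generators are
pure functions of their seed and restore the global RNG state.

Noise amplitudes were calibrated once so the end-to-end recovery checks pass
with margin but not trivially: across 12 probe seeds, the worst-case focus
localization error is ~3.7 mm (criterion: one smoothing FWHM, 6 mm) and the
worst condition-ratio error ~3.5% (criterion: 5%).

What passing does **not** show: the verification correlations on this fixture
run ~0.99 — higher than the ~0.8 typical of real arrays — because with 8
sparse channels the sphere at a channel's peak is reconstructed mostly from
that channel, so its noise appears on both sides of the correlation. Real
36–40-channel arrays mix channels more and add physiology the model lacks.
The fixture validates the pipeline's algebra, contracts, and parameter
recovery, not photon physics or real-data effect sizes.

## Problem sizes and budgets

The default fixture (40^3 voxels, 8 channels x 2 wavelengths, 120 s at 50 Hz
down-sampled to 25 Hz) runs the full pipeline in well under a minute on one
core; the test suite and the acceptance script each run it once. Matrix
sizes: `A` is 16 x ~8800 after thresholding; inversion solves a 8 x 8
system per wavelength (measurement-space form).

## Known limitations

* Sensitivity surrogates are geometric, not photon transport; absolute uM
  scales are internally consistent but not physically calibrated (no partial
  pathlength correction).
* Motion-artifact detection/correction is out of scope by design (hook only).
* SNIRF/HDF5 I/O is not provided; the documented CSV dialect
  (`write_channel_csv()`/`read_channel_csv()`) is the on-disk channel format.
* Group-space registration and group statistics are out of scope; betas can
  be exported as NIFTI for external tools.
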