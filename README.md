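# fnirsdot

Volumetric image reconstruction of functional near-infrared spectroscopy
(fNIRS) data in R.

Channel-space fNIRS analyses assume every participant's source–detector pairs
sample the same cortex — an assumption broken by cap placement, head shape,
and digitization error. `fnirsdot` takes channel recordings into voxel space
instead, for researchers running diffuse optical tomography (DOT) studies or
building pipelines for them. It covers the full chain:

* **Digitization cleaning** — read Polhemus ASCII digitizations, build a
  per-cap-size consensus template by mutual rigid (Kabsch) alignment, repair
  stylus slips by three-step / iterative / head-wise correction, and export
  `digpts.txt` files for anatomy tools.
* **Channel preprocessing** — prune channels outside 80–130 dB, convert to
  optical density, reject triggers near externally detected motion artifacts
  (−1 to +18 s window), zero-phase band-pass 0.016–0.5 Hz, global signal
  regression per wavelength, Fourier down-sampling to 25 Hz.
* **Light model** — vectorize per-measurement sensitivity volumes (NIFTI)
  into a measurements × voxels matrix `A`, keeping voxels above 0.01 of the
  global maximum (the `good_vox` index set; typically a 5–10× size
  reduction).
* **Reconstruction** — spatially variant Tikhonov inversion
  `min ||y − Ax||² + λ₁||Lx||²` with `diag(L) = sqrt(diag(AᵀA) + λ₂)`
  (defaults λ₁ = 0.01, λ₂ = 0.1), per wavelength, with Gaussian smoothing
  (3–10 mm FWHM) and spectroscopic conversion to HbO₂/HbR/HbT via the 2×2
  extinction system.
* **Verification** — 2 cm spheres at each channel's cortex-masked
  sensitivity maximum; Pearson correlation of sphere-mean image series
  against the channel's own chromophore series, pass criterion r > 0.25.
* **GLM** — double-gamma HRF (delays 4/15 s, dispersions 1, ratio 6, 16 s
  kernel), boxcar or impulse event models, voxelwise OLS, event-count-
  weighted beta averaging across runs.
* **Synthetic data** — seeded generators for layered head phantoms, probe
  layouts, banana-shaped sensitivity surrogates, noisy digitizations, and
  channel recordings with known injected activation, so everything above is
  testable end to end with no recordings.

## Worked example

A complete run on the synthetic phantom — simulate, preprocess, reconstruct,
verify, and fit the GLM:

```r
library(fnirsdot)

spec    <- phantom_spec()                      # 40^3 voxels @ 2 mm, layered head
phantom <- generate_phantom_head(spec)
probe   <- probe_layout(spec)                  # 8 source-detector pairs, 690/830 nm
model   <- vectorize_sensitivity(generate_sensitivity(phantom, probe),
                                 threshold_frac = 0.01,
                                 voxel_size_mm = spec$voxel_size_mm,
                                 measurements = probe$measurements)

cortex <- phantom$labels == 3L                 # gray-matter mask
focus  <- cortical_peak_voxel(model, cortex, channel_row = 1)
sim <- generate_channel_data(model, default_paradigm(),
  activation = list(center = focus, sigma_mm = 4,
                    hbo = c(A = 1, B = 0.5), hbr = c(A = -0.3, B = -0.15)),
  event_extent_s = 10, seed = 1)

rec    <- preprocess_recording(sim$recording)  # prune, OD, band-pass, GSR, 25 Hz
recon  <- reconstruct_recording(model, rec, lambda1 = 0.01, lambda2 = 0.1,
                                fwhm_mm = 6)
report <- verify_reconstruction(recon, rec, model, cortex)

hrf <- gamma_hrf(fs = rec$acquisition_fs)
X <- build_design(rec$paradigm, hrf, rec$acquisition_fs,
                  round(ncol(recon$hbo) * rec$acquisition_fs / rec$fs),
                  event_extent_s = 10)
X <- resample_design(filter_design(X, rec$acquisition_fs), ncol(recon$hbo))
fit <- fit_glm(recon$hbo, X)

com <- activation_centroid(fit$betas[, "A"], model, mask = cortex)
truth_mm <- (arrayInd(focus, model$dim) - (model$dim + 1) / 2) * model$voxel_size_mm
sqrt(sum((com$mm - truth_mm)^2))
```

which prints:

```
<head_volume> 40x40x40 @ 2 mm: background=39536, scalp/skull=10136, CSF=2792, gray=5920, white=5616
<sensitivity_model> 16 measurements x 8752 retained voxels (of 64000; 7.3x reduction), threshold 0.01 of max
<channel_recording> 6000 frames x 16 measurements @ 50 Hz (intensity), 16 good, 10 trigger(s)
<recon_result> 8752 voxels x 3000 frames @ 25 Hz; HbO2/HbR/HbT (uM); lambda1 = 0.01, lambda2 = 0.1, smoothed 6 mm
<verification_report> 16/16 correlations > 0.25 (mean r of passing subset: 1.000)
<glm_result> 8752 voxels, 3 regressor(s): intercept, A, B; 2997 residual df
localization error: 3.5 mm
```

Reading the output: thresholding kept 8752 of 64,000 voxels (7.3× smaller
model); all 16 channel-vs-image correlations clear the 0.25 criterion; and
the dominant cluster of the condition-A HbO₂ beta map sits 3.5 mm from the
voxel where activation was injected — within the 6 mm smoothing kernel. The
sphere-averaged betas around the focus recover the injected 2:1 condition
amplitude ratio to within a few percent (see `scripts/acceptance.R`).

The same chain can be driven stage by stage with file hand-off via
`run_pipeline(pipeline_config(), out_dir)`, or from a shell through the thin
front end `inst/cli/fnirsdot.R` (subcommands `simulate`, `caps`,
`lightmodel`, `preprocess`, `reconstruct`, `glm`, `verify`, `run`).

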