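# Seeded synthetic generators for every input the pipeline consumes: layered
# head phantoms, banana-shaped sensitivity surrogates, noisy digitizations,
# and channel recordings with known injected activation. All are pure
# functions of (spec, seed); RNG state is saved and restored.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
      else assign(".Random.seed", old, .GlobalEnv)
    })
    set.seed(seed)
  }
  force(code)
}

#' Phantom head specification
#'
#' Geometry of a concentric-layer spherical head phantom: a white-matter core
#' wrapped in gray matter, CSF, and a combined scalp/skull shell, embedded in
#' background. Default layer radii (22/28/30/36 mm in a 40^3 volume of 2 mm
#' voxels) give a desk-scale head with every tissue class represented.
#'
#' @param shape Volume dimensions (voxels).
#' @param voxel_size_mm Isotropic voxel size.
#' @param r_white_mm,r_gray_mm,r_csf_mm,r_head_mm Outer radii of the white,
#'   gray, CSF and scalp/skull layers (strictly increasing).
#' @export
phantom_spec <- function(shape = c(40, 40, 40), voxel_size_mm = 2,
                         r_white_mm = 22, r_gray_mm = 28, r_csf_mm = 30,
                         r_head_mm = 36) {
  stopifnot(length(shape) == 3L, all(shape >= 1), voxel_size_mm > 0,
            r_white_mm > 0, r_gray_mm > r_white_mm, r_csf_mm > r_gray_mm,
            r_head_mm > r_csf_mm)
  structure(list(shape = as.integer(shape), voxel_size_mm = voxel_size_mm,
                 r_white_mm = r_white_mm, r_gray_mm = r_gray_mm,
                 r_csf_mm = r_csf_mm, r_head_mm = r_head_mm),
            class = "phantom_spec")
}

# voxel-center coordinates (mm) relative to the volume center
voxel_coords_mm <- function(shape, voxel_size_mm) {
  ctr <- (shape + 1) / 2
  g <- arrayInd(seq_len(prod(shape)), shape)
  sweep(g, 2, ctr) * voxel_size_mm
}

#' Generate a segmented head phantom
#'
#' Labels: 0 background, 1 scalp/skull, 2 CSF, 3 gray matter, 4 white matter.
#' Deterministic given the spec.
#'
#' @param spec A [phantom_spec()].
#' @return A `head_volume`: `labels` (3D integer array), `voxel_size_mm`,
#'   `spec`.
#' @export
generate_phantom_head <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  r <- sqrt(rowSums(voxel_coords_mm(spec$shape, spec$voxel_size_mm)^2))
  lab <- integer(length(r))
  lab[r <= spec$r_head_mm]  <- 1L
  lab[r <= spec$r_csf_mm]   <- 2L
  lab[r <= spec$r_gray_mm]  <- 3L
  lab[r <= spec$r_white_mm] <- 4L
  if (all(lab == 0L))
    stop_fnirsdot("phantom contains no tissue voxels (head smaller than a voxel?)",
                  "empty_model")
  structure(list(labels = array(lab, dim = spec$shape),
                 voxel_size_mm = spec$voxel_size_mm, spec = spec),
            class = "head_volume")
}

#' @export
print.head_volume <- function(x, ...) {
  tb <- table(factor(x$labels, levels = 0:4,
                     labels = c("background", "scalp/skull", "CSF", "gray", "white")))
  cat("<head_volume>", paste(dim(x$labels), collapse = "x"),
      sprintf("@ %g mm:", x$voxel_size_mm),
      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Probe layout on a phantom scalp
#'
#' Places optodes on the scalp sphere: `n_sources` sources on a ring at polar
#' angle `theta_source_deg` and as many detectors on a ring at
#' `theta_detector_deg`, azimuths evenly spaced and the detector ring rotated
#' half a step. Each source is paired with its `detectors_per_source` nearest
#' detectors, giving an overlapping array like the multi-distance grids real
#' imaging probes use.
#'
#' @param spec A [phantom_spec()].
#' @param n_sources Sources (= detectors) on each ring (default 8).
#' @param detectors_per_source Channels per source (default 1, a disjoint
#'   array; 2 or more gives an overlapping multi-distance grid).
#' @param wavelengths_nm Wavelength pair measured on every channel.
#' @param theta_source_deg,theta_detector_deg Polar angles of the two rings.
#' @return A `probe_layout`: `sources`, `detectors` (n x 3 mm, volume-center
#'   origin), `channels` (data.frame), `measurements` (a [measurement_list()]
#'   with channels x wavelengths rows, wavelength fastest).
#' @export
probe_layout <- function(spec, n_sources = 8, detectors_per_source = 1,
                         wavelengths_nm = c(690, 830),
                         theta_source_deg = 20, theta_detector_deg = 60) {
  stopifnot(inherits(spec, "phantom_spec"), n_sources >= 1,
            detectors_per_source >= 1, detectors_per_source <= n_sources)
  az <- (seq_len(n_sources) - 1) * 2 * pi / n_sources
  on_sphere <- function(theta_deg, az) {
    th <- theta_deg * pi / 180
    spec$r_head_mm * cbind(sin(th) * cos(az), sin(th) * sin(az), cos(th))
  }
  src <- on_sphere(theta_source_deg, az)
  det <- on_sphere(theta_detector_deg, az)
  ch <- data.frame(
    source = rep(seq_len(n_sources), each = detectors_per_source),
    detector = as.vector(vapply(seq_len(n_sources), function(k)
      as.integer(1L + (k - 1L + seq_len(detectors_per_source) - 1L) %% n_sources),
      integer(detectors_per_source))))
  sep <- sqrt(rowSums((src[ch$source, , drop = FALSE] -
                         det[ch$detector, , drop = FALSE])^2))
  ml <- measurement_list(
    source = rep(ch$source, each = length(wavelengths_nm)),
    detector = rep(ch$detector, each = length(wavelengths_nm)),
    wavelength_nm = rep(wavelengths_nm, nrow(ch)),
    sep3d_mm = rep(sep, each = length(wavelengths_nm)))
  structure(list(sources = src, detectors = det, channels = ch,
                 wavelengths_nm = wavelengths_nm, measurements = ml),
            class = "probe_layout")
}

#' Generate surrogate sensitivity volumes for a probe
#'
#' For each measurement, a non-negative "banana": the product of Gaussian
#' distance-decay kernels from the source and detector scalp positions,
#' masked to tissue and peak-normalized. This is a geometric surrogate for
#' photon-transport sensitivity — non-negative, channel-localized, and
#' overlapping across channels, which is all the downstream linear algebra
#' requires. The peak falls at the tissue voxel nearest the source-detector
#' midpoint (between the optodes, below the scalp surface); a zero-separation
#' pair degenerates to a single blob under the optode. The decay scale is
#' perturbed per wavelength so the two wavelengths' volumes are distinct.
#'
#' @param phantom A `head_volume`.
#' @param probe A [probe_layout()].
#' @param decay_mm Gaussian decay scale (default 10 mm).
#' @param wavelength_dilation Fractional increase of the decay scale per
#'   wavelength step, emulating the slightly deeper penetration of the longer
#'   wavelength. Default 0: shared profiles per channel. At desk scale the
#'   spectroscopic differencing of two dilated profiles dominates localization
#'   error, so wavelength dependence is off unless explicitly requested.
#' @return List of 3D arrays ordered as `probe$measurements`.
#' @export
generate_sensitivity <- function(phantom, probe, decay_mm = 10,
                                 wavelength_dilation = 0) {
  stopifnot(inherits(phantom, "head_volume"), inherits(probe, "probe_layout"))
  shape <- dim(phantom$labels)
  xyz <- voxel_coords_mm(shape, phantom$voxel_size_mm)
  tissue <- as.numeric(phantom$labels) > 0
  ml <- probe$measurements
  wl_scale <- 1 + wavelength_dilation *
    (match(ml$wavelength_nm, probe$wavelengths_nm) - 1)
  lapply(seq_len(nrow(ml)), function(i) {
    s <- probe$sources[ml$source[i], ]
    d <- probe$detectors[ml$detector[i], ]
    rho <- decay_mm * wl_scale[i]
    ds2 <- rowSums(sweep(xyz, 2, s)^2)
    dd2 <- rowSums(sweep(xyz, 2, d)^2)
    v <- exp(-(ds2 + dd2) / (2 * rho^2))
    v[!tissue] <- 0
    m <- max(v)
    if (m > 0) v <- v / m
    array(v, dim = shape)
  })
}

# Rodrigues rotation matrix about a unit axis.
rotation_matrix <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

#' Generate noisy digitizations from a template layout
#'
#' Simulates digitizer output: the template's points plus iid Gaussian jitter,
#' a rigid misorientation per cap (random rotation and shift), and, per cap,
#' `n_outlier_points` points displaced by `outlier_shift_cm` in a random
#' direction — the signature of a digitizer slip. The true outlier indices are
#' attached as attribute `outliers` (a list per cap) for correction-recall
#' checks.
#'
#' @param template_cap A cap (or template) providing the layout.
#' @param n Number of caps.
#' @param noise_sd_cm Per-point jitter SD (default 0.3 cm).
#' @param n_outlier_points Slipped points per cap (default 0).
#' @param outlier_shift_cm Slip magnitude (default 15 cm).
#' @param max_rot_deg,max_shift_cm Rigid misorientation bounds.
#' @param seed RNG seed.
#' @param id_prefix Prefix for the generated cap ids.
#' @return List of caps with attribute `outliers`.
#' @export
generate_caps <- function(template_cap, n, noise_sd_cm = 0.3,
                          n_outlier_points = 0, outlier_shift_cm = 15,
                          max_rot_deg = 15, max_shift_cm = 3, seed = 1,
                          id_prefix = "sim") {
  stopifnot(n >= 1, noise_sd_cm >= 0, n_outlier_points >= 0)
  pts0 <- template_points(template_cap)
  with_seed(seed, {
    outliers <- vector("list", n)
    caps <- lapply(seq_len(n), function(i) {
      R <- rotation_matrix(stats::rnorm(3), stats::runif(1, 0, max_rot_deg) * pi / 180)
      shift <- stats::runif(3, -max_shift_cm, max_shift_cm)
      pts <- sweep(pts0 %*% t(R), 2, shift, `+`) +
        matrix(stats::rnorm(length(pts0), 0, noise_sd_cm), nrow(pts0))
      if (n_outlier_points > 0) {
        idx <- sample(nrow(pts0), n_outlier_points)
        dir <- matrix(stats::rnorm(3 * n_outlier_points), ncol = 3)
        dir <- dir / sqrt(rowSums(dir^2))
        pts[idx, ] <- pts[idx, ] + dir * outlier_shift_cm
        outliers[[i]] <<- sort(idx)
      } else outliers[[i]] <<- integer(0)
      new_cap(pts, template_cap$roles, template_cap$labels,
              cap_id = sprintf("%s%02d", id_prefix, i),
              cap_size_cm = template_cap$cap_size_cm)
    })
    attr(caps, "outliers") <- outliers
    caps
  })
}

#' Generate a synthetic channel recording with known activation
#'
#' Forward-simulates the whole measurement chain: condition regressors (event
#' train convolved with the HRF) scale a Gaussian activation blob in voxel
#' space per chromophore; chromophore concentrations become absorption changes
#' through the extinction coefficients; absorption maps to measurement optical
#' density through `y = A x`; a shared sinusoidal "systemic physiology"
#' component (with per-channel gain jitter, so global signal regression can
#' remove it) and white noise are added; and the result is exponentiated to
#' raw intensities around per-channel baselines. The clean signal and all
#' ground-truth quantities are returned alongside.
#'
#' @param model A `sensitivity_model` with a measurement list.
#' @param paradigm Data frame `onset_s`, `condition`.
#' @param activation List: `center` (linear voxel index into the full volume),
#'   `sigma_mm` (blob SD, default 4), `hbo`, `hbr` (named per-condition peak
#'   amplitudes, uM).
#' @param fs,duration_s Sampling rate and length of the recording.
#' @param hrf HRF kernel at `fs`; default [gamma_hrf()] defaults.
#' @param event_extent_s Boxcar duration per event (s).
#' @param white_sd OD white-noise SD per sample (default 2e-4, a
#'   research-grade CW system with good optode contact).
#' @param physio_amp,physio_freq Global physiology amplitude (OD) and
#'   frequency (Hz); defaults 0.02 and 0.1 (Mayer-wave-scale systemic
#'   oscillation, larger than the evoked response as in real recordings).
#' @param baseline_db Channel baseline level, dB (default 100).
#' @param table Extinction table override.
#' @param seed RNG seed.
#' @return List: `recording` (intensity-unit [channel_recording()]) and
#'   `truth` (clean OD signal, per-condition regressors, blob weights over
#'   `good_vox`, activation spec, signal-bearing channel rows).
#' @export
generate_channel_data <- function(model, paradigm, activation,
                                  fs = 50, duration_s = 120, hrf = NULL,
                                  event_extent_s = 0, white_sd = 2e-4,
                                  physio_amp = 0.02, physio_freq = 0.1,
                                  baseline_db = 100, table = NULL, seed = 1) {
  stopifnot(inherits(model, "sensitivity_model"), !is.null(model$measurements))
  n <- round(duration_s * fs)
  if (is.null(hrf)) hrf <- gamma_hrf(fs)
  sigma_mm <- if (is.null(activation$sigma_mm)) 4 else activation$sigma_mm
  conds <- unique(as.character(paradigm$condition))
  stopifnot(all(conds %in% names(activation$hbo)),
            all(conds %in% names(activation$hbr)))
  X <- build_design(paradigm, hrf, fs, n, event_extent_s, intercept = FALSE)
  X <- X[, conds, drop = FALSE]
  # one common scale so the largest regressor peaks at 1: amplitudes are then
  # peak uM and the ratio between conditions is preserved exactly
  X <- X / max(abs(X))

  xyz <- voxel_coords_mm(model$dim, model$voxel_size_mm)[model$good_vox, , drop = FALSE]
  ctr <- voxel_coords_mm(model$dim, model$voxel_size_mm)[activation$center, ]
  blob <- exp(-rowSums(sweep(xyz, 2, ctr)^2) / (2 * sigma_mm^2))

  hbo_t <- as.numeric(X %*% unlist(activation$hbo[conds]))   # frames
  hbr_t <- as.numeric(X %*% unlist(activation$hbr[conds]))
  wl <- sort(unique(model$measurements$wavelength_nm))
  stopifnot(length(wl) == 2L)
  ext <- extinction_coefficients(wl, table)
  E <- as.matrix(ext[, c("HbO2", "HbR")])
  # y[i, t] = A[i, ] %*% (blob * (E_hbo hbo_t + E_hbr hbr_t)); separable in
  # space and time, so collapse the spatial part first.
  Ablob <- as.numeric(model$A %*% blob)                      # per measurement
  wi <- match(model$measurements$wavelength_nm, wl)
  clean <- (Ablob * E[wi, 1]) %o% hbo_t + (Ablob * E[wi, 2]) %o% hbr_t

  nm <- nrow(model$A)
  with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    physio <- rep(1, nm) %o% (physio_amp * sin(2 * pi * physio_freq *
                                                 seq_len(n) / fs + phase))
    noise <- matrix(stats::rnorm(nm * n, 0, white_sd), nm, n)
    od <- clean + physio + noise
    i0 <- 10^(baseline_db / 20)
    intens <- t(i0 * exp(-od))
    rec <- channel_recording(intens, fs, model$measurements, paradigm,
                             unit = "intensity")
    sig_rms <- sqrt(rowMeans(clean^2))
    truth <- list(clean_od = clean, design = X, blob = blob,
                  activation = c(activation, list(sigma_mm = sigma_mm)),
                  center_mm = ctr,
                  signal_bearing = which(sig_rms > 0.1 * max(sig_rms)))
    list(recording = rec, truth = truth)
  })
}
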