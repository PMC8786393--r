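# Channel-space preprocessing. Canonical order:
#   prune -> optical density -> (motion-correction hook) -> trigger rejection
#   -> bandpass -> global signal regression -> resample.
# Each stage returns a new recording; only reject_triggers touches the
# paradigm.

#' Prune channels by mean signal level
#'
#' Flags measurements whose mean raw intensity, expressed in dB as
#' `20 * log10(mean intensity / reference)`, falls outside `[low_db, high_db]`.
#' Channels outside the window (too dim: poor coupling; too bright: saturated)
#' get `good_meas = FALSE`; nothing is removed from the data matrix.
#'
#' @param rec Intensity-unit [channel_recording()].
#' @param low_db,high_db Acceptance window, default 80 and 130 dB.
#' @param reference Intensity corresponding to 0 dB (default 1 unit).
#' @export
prune_channels <- function(rec, low_db = 80, high_db = 130, reference = 1) {
  stopifnot(inherits(rec, "channel_recording"))
  if (rec$unit != "intensity")
    stop_fnirsdot("pruning operates on raw intensity data", "unit_error")
  mu <- colMeans(rec$data)
  if (any(mu <= 0))
    stop_fnirsdot("non-positive mean intensity; cannot convert to dB", "unit_error")
  db <- 20 * log10(mu / reference)
  rec$good_meas <- rec$good_meas & db >= low_db & db <= high_db
  rec
}

#' Convert raw intensities to optical density
#'
#' Per channel, `OD(t) = -ln(I(t) / mean(I))`, using the channel's temporal
#' mean as baseline (natural log, the convention of the common channel-space
#' processing tools; substitute log10 data upstream if preferred). OD is
#' invariant to rescaling the intensities.
#'
#' @param rec Intensity-unit recording with strictly positive samples.
#' @export
intensity_to_od <- function(rec) {
  stopifnot(inherits(rec, "channel_recording"))
  if (rec$unit != "intensity")
    stop_fnirsdot("data are already in OD units", "unit_error")
  bad <- which(apply(rec$data <= 0, 2, any))
  if (length(bad))
    stop_fnirsdot(sprintf("non-positive intensity sample in channel(s) %s",
                          paste(bad, collapse = ", ")), "unit_error")
  rec$data <- -log(sweep(rec$data, 2, colMeans(rec$data), `/`))
  rec$unit <- "od"
  rec
}

# filtfilt with odd reflection padding; plain filtfilt leaves long edge
# transients at cutoffs far below Nyquist (a 0.016 Hz highpass rings for ~1 min).
filtfilt_padded <- function(flt, x) {
  n <- length(x)
  np <- min(n - 1L, (3L * n) %/% 4L)
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(flt, c(pre, x, post))
  y[(np + 1):(np + n)]
}

#' Zero-phase band-pass filter
#'
#' Third-order Butterworth high-pass and low-pass applied forward-backward
#' (zero phase, squared magnitude response), with reflection padding to tame
#' edge transients. Removes DC; pass-band gain is ~1.
#'
#' @param rec A recording.
#' @param f_hp,f_lp High-/low-pass cutoffs in Hz, default 0.016 and 0.5.
#' @param order Butterworth order per section (default 3).
#' @export
bandpass <- function(rec, f_hp = 0.016, f_lp = 0.5, order = 3) {
  stopifnot(inherits(rec, "channel_recording"))
  nyq <- rec$fs / 2
  if (!(f_hp > 0 && f_hp < f_lp && f_lp < nyq))
    stop_fnirsdot(sprintf("need 0 < f_hp < f_lp < fs/2 = %g Hz", nyq),
                  "parameter_error")
  hp <- signal::butter(order, f_hp / nyq, type = "high")
  lp <- signal::butter(order, f_lp / nyq, type = "low")
  rec$data <- apply(rec$data, 2, function(x) filtfilt_padded(lp, filtfilt_padded(hp, x)))
  rec
}

#' Remove triggers contaminated by motion artifacts
#'
#' Motion-artifact *detection* is deliberately external (published algorithms
#' exist in channel-space processing suites); this hook consumes their output.
#' A trigger at time t is removed when any supplied artifact interval
#' intersects the window `[t + window[1], t + window[2]]` seconds (default -1
#' to +18 s, endpoints inclusive).
#'
#' @param rec A recording.
#' @param artifact_intervals Two-column matrix/data.frame of artifact
#'   `(start_s, end_s)` intervals; zero rows means keep everything.
#' @param window Length-2 numeric, seconds relative to each trigger.
#' @export
reject_triggers <- function(rec, artifact_intervals, window = c(-1, 18)) {
  stopifnot(inherits(rec, "channel_recording"), length(window) == 2L,
            window[1] < window[2])
  if (nrow(rec$paradigm) == 0L || NROW(artifact_intervals) == 0L) return(rec)
  ai <- as.matrix(artifact_intervals)[, 1:2, drop = FALSE]
  hit <- vapply(rec$paradigm$onset_s, function(t) {
    any(ai[, 1] <= t + window[2] & ai[, 2] >= t + window[1])
  }, logical(1))
  rec$paradigm <- rec$paradigm[!hit, , drop = FALSE]
  rec
}

#' Global signal regression
#'
#' For each wavelength separately, computes the mean time series over the
#' low-noise (good) channels at that wavelength and regresses it (with an
#' intercept) out of every channel at that wavelength. The global mean is a
#' surrogate for systemic physiology shared across the array; residuals are
#' orthogonal to it by least squares.
#'
#' @param rec OD-unit recording with `good_meas` marking low-noise channels.
#' @export
global_signal_regression <- function(rec) {
  stopifnot(inherits(rec, "channel_recording"))
  if (rec$unit != "od")
    stop_fnirsdot("global signal regression expects OD data", "unit_error")
  wls <- unique(rec$measurements$wavelength_nm)
  gmat <- matrix(NA_real_, nrow(rec$data), length(wls),
                 dimnames = list(NULL, paste0("g", wls)))
  for (k in seq_along(wls)) {
    cols <- which(rec$measurements$wavelength_nm == wls[k])
    good <- cols[rec$good_meas[cols]]
    if (length(good) == 0L)
      stop_fnirsdot(sprintf("no good channels at %g nm", wls[k]), "empty_model")
    g <- rowMeans(rec$data[, good, drop = FALSE])
    X <- cbind(1, g)
    beta <- qr.solve(X, rec$data[, cols, drop = FALSE])
    rec$data[, cols] <- rec$data[, cols, drop = FALSE] - X %*% beta
    gmat[, k] <- g
  }
  # kept for use as GLM nuisance regressors: the regression removes the task
  # signal's projection onto g as well, and downstream model fits stay
  # unbiased only if they account for the same subspace
  rec$global_signals <- gmat
  rec
}

# Fourier-domain resampling (spectrum truncation/zero-padding), exact for
# band-limited content; used instead of polyphase filtering for its flat
# pass-band.
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  nh <- min(n, n_out) %/% 2
  Y[1:(nh + 1)] <- X[1:(nh + 1)]
  if (nh > 0) Y[(n_out - nh + 1):n_out] <- X[(n - nh + 1):n]
  if (min(n, n_out) %% 2 == 0) {
    # split the (shared) Nyquist bin to keep the signal real
    if (n_out < n) {
      Y[nh + 1] <- X[nh + 1] + X[n - nh + 1]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Down-sample a recording
#'
#' Anti-aliased Fourier-domain resampling of every channel to `target_fs`.
#' Duration is preserved to within one sample and paradigm times (in seconds)
#' are untouched. Up-sampling is refused by default — reconstruction only ever
#' needs to go down (e.g. to 25 Hz).
#'
#' @param rec A recording.
#' @param target_fs Target rate in Hz, default 25; must not exceed `rec$fs`.
#' @param allow_upsample Permit `target_fs > fs` if explicitly requested.
#' @export
resample_recording <- function(rec, target_fs = 25, allow_upsample = FALSE) {
  stopifnot(inherits(rec, "channel_recording"), target_fs > 0)
  if (target_fs > rec$fs && !allow_upsample)
    stop_fnirsdot("refusing to upsample (set allow_upsample = TRUE to force)",
                  "parameter_error")
  if (target_fs == rec$fs) return(rec)
  n_out <- round(nrow(rec$data) * target_fs / rec$fs)
  rec$data <- apply(rec$data, 2, fft_resample, n_out = n_out)
  if (!is.null(rec$global_signals))
    rec$global_signals <- apply(rec$global_signals, 2, fft_resample, n_out = n_out)
  if (is.null(rec$acquisition_fs)) rec$acquisition_fs <- rec$fs
  rec$fs <- target_fs
  rec
}

#' Run the canonical channel-space preprocessing chain
#'
#' prune -> OD -> (artifact hook) -> trigger rejection -> bandpass ->
#' global signal regression -> resample, with the standard defaults.
#'
#' @param rec Raw intensity recording.
#' @param artifact_intervals Passed to [reject_triggers()]; default none.
#' @param low_db,high_db,f_hp,f_lp,window,target_fs Stage parameters.
#' @param gsr Apply global signal regression (default TRUE).
#' @export
preprocess_recording <- function(rec, artifact_intervals = NULL,
                                 low_db = 80, high_db = 130,
                                 f_hp = 0.016, f_lp = 0.5,
                                 window = c(-1, 18), target_fs = 25,
                                 gsr = TRUE) {
  rec <- prune_channels(rec, low_db, high_db)
  rec <- intensity_to_od(rec)
  if (!is.null(artifact_intervals))
    rec <- reject_triggers(rec, artifact_intervals, window)
  rec <- bandpass(rec, f_hp, f_lp)
  if (gsr) rec <- global_signal_regression(rec)
  resample_recording(rec, min(target_fs, rec$fs))
}
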