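#' Double-gamma hemodynamic response function
#'
#' The SPM-style modified gamma kernel: the difference of two gamma densities,
#' a response component minus a scaled undershoot,
#' `h(t) = g(t; delay_r/disp_r, disp_r) - g(t; delay_u/disp_u, disp_u)/ratio`,
#' sampled at `fs`, truncated at `kernel_length_s`, shifted by `onset`, and
#' normalized to unit peak. The mode of the response gamma sits at
#' `delay_response - dispersion_response` seconds.
#'
#' @param fs Sampling rate, Hz.
#' @param delay_response,delay_undershoot Gamma delays, s (defaults 4 and 15).
#' @param dispersion_response,dispersion_undershoot Dispersions, s (defaults 1).
#' @param ratio Response-to-undershoot ratio (default 6).
#' @param onset Onset shift, s (default 0).
#' @param kernel_length_s Kernel support, s (default 16).
#' @return Numeric kernel of `kernel_length_s * fs` samples, with attributes
#'   `fs` and `spec`.
#' @export
gamma_hrf <- function(fs, delay_response = 4, delay_undershoot = 15,
                      dispersion_response = 1, dispersion_undershoot = 1,
                      ratio = 6, onset = 0, kernel_length_s = 16) {
  if (dispersion_response <= 0 || dispersion_undershoot <= 0)
    stop_fnirsdot("dispersions must be positive", "parameter_error")
  stopifnot(fs > 0, kernel_length_s > 0, ratio > 0)
  t <- seq(0, kernel_length_s - 1 / fs, by = 1 / fs) - onset
  h <- stats::dgamma(t, shape = delay_response / dispersion_response,
                     scale = dispersion_response) -
       stats::dgamma(t, shape = delay_undershoot / dispersion_undershoot,
                     scale = dispersion_undershoot) / ratio
  h <- h / max(h)
  structure(h, fs = fs,
            spec = list(delay_response = delay_response,
                        delay_undershoot = delay_undershoot,
                        dispersion_response = dispersion_response,
                        dispersion_undershoot = dispersion_undershoot,
                        ratio = ratio, onset = onset,
                        kernel_length_s = kernel_length_s))
}

#' Build a GLM design matrix from a stimulus paradigm
#'
#' Per regressor, an event train (impulses, or boxcars of `event_extent_s`
#' seconds) is convolved with the HRF kernel and truncated to `n_frames`. By
#' default each condition gets its own regressor; `condition_map` (a named
#' character vector condition -> regressor name) collapses conditions onto
#' shared regressors when the analysis calls for it.
#'
#' @param paradigm Data frame with `onset_s`, `condition`.
#' @param hrf Kernel sampled at `fs` (see [gamma_hrf()]), or any numeric
#'   vector.
#' @param fs Frame rate of the data, Hz.
#' @param n_frames Number of data frames.
#' @param event_extent_s Boxcar duration per event, s; 0 models each event as
#'   an impulse.
#' @param condition_map Optional named character vector mapping condition
#'   labels to regressor names.
#' @param intercept Prepend a constant column (default TRUE).
#' @return `n_frames` x p design matrix with named columns; attribute
#'   `event_counts` gives the number of events entering each task regressor.
#' @export
build_design <- function(paradigm, hrf, fs, n_frames, event_extent_s = 0,
                         condition_map = NULL, intercept = TRUE) {
  if (is.null(paradigm) || nrow(paradigm) == 0L)
    stop_fnirsdot("empty paradigm: no events to model", "paradigm_invalid")
  if (any(paradigm$onset_s >= n_frames / fs) || any(paradigm$onset_s < 0))
    stop_fnirsdot("trigger times must lie within the recording", "paradigm_invalid")
  stopifnot(event_extent_s >= 0)
  regressor_of <- if (is.null(condition_map)) {
    stats::setNames(nm = unique(as.character(paradigm$condition)))
  } else condition_map
  cond <- as.character(paradigm$condition)
  if (!all(cond %in% names(regressor_of)))
    stop_fnirsdot("condition_map does not cover all paradigm conditions",
                  "paradigm_invalid")
  regs <- unique(unname(regressor_of))
  X <- matrix(0, n_frames, length(regs), dimnames = list(NULL, regs))
  counts <- stats::setNames(integer(length(regs)), regs)
  n_box <- max(1L, round(event_extent_s * fs))
  for (i in seq_len(nrow(paradigm))) {
    r <- regressor_of[[cond[i]]]
    on <- 1L + round(paradigm$onset_s[i] * fs)
    idx <- on:min(n_frames, on + n_box - 1L)
    X[idx, r] <- X[idx, r] + 1
    counts[r] <- counts[r] + 1L
  }
  # time-domain convolution (exact zeros outside the support, unlike FFT)
  k <- as.numeric(hrf)
  p <- length(k)
  for (r in regs) {
    conv <- stats::filter(c(numeric(p), X[, r]), k, method = "convolution",
                          sides = 1)
    X[, r] <- conv[(p + 1):(p + n_frames)]
  }
  if (intercept) {
    X <- cbind(intercept = 1, X)
  }
  attr(X, "event_counts") <- counts
  X
}

#' Apply the data's temporal filtering to a design matrix
#'
#' When the voxel series were band-pass filtered in channel space, the GLM is
#' only unbiased if the task regressors pass through the same filter; this
#' applies the identical zero-phase Butterworth pair to every non-intercept
#' column. Attributes (event counts) are preserved.
#'
#' @param design Matrix from [build_design()].
#' @param fs Frame rate, Hz.
#' @param f_hp,f_lp,order Filter parameters, as in [bandpass()].
#' @export
filter_design <- function(design, fs, f_hp = 0.016, f_lp = 0.5, order = 3) {
  nyq <- fs / 2
  stopifnot(f_hp > 0, f_hp < f_lp, f_lp < nyq)
  hp <- signal::butter(order, f_hp / nyq, type = "high")
  lp <- signal::butter(order, f_lp / nyq, type = "low")
  keep <- colnames(design) != "intercept"
  out <- design
  out[, keep] <- apply(design[, keep, drop = FALSE], 2, function(x)
    filtfilt_padded(lp, filtfilt_padded(hp, x)))
  attr(out, "event_counts") <- attr(design, "event_counts")
  out
}

#' Resample a design matrix to the data's frame count
#'
#' When channel data were down-sampled before reconstruction, regressors built
#' (and filtered) at the acquisition rate must go through the same resampling
#' operator as the data, or small timing mismatches leak into the betas of
#' overlapping regressors. Applies the Fourier-domain resampler used by
#' [resample_recording()] to every column.
#'
#' @param design Matrix from [build_design()] (at the acquisition rate).
#' @param n_frames Frame count of the resampled data.
#' @export
resample_design <- function(design, n_frames) {
  out <- apply(design, 2, fft_resample, n_out = n_frames)
  colnames(out) <- colnames(design)
  attr(out, "event_counts") <- attr(design, "event_counts")
  out
}

#' Append nuisance regressors to a design
#'
#' Adds columns (e.g. the global signals recorded by
#' [global_signal_regression()]) that the fit should account for without
#' counting them as task conditions.
#'
#' @param design Matrix from [build_design()].
#' @param nuisance Matrix or vector, one row per frame.
#' @export
add_nuisance <- function(design, nuisance) {
  nuisance <- as.matrix(nuisance)
  stopifnot(nrow(nuisance) == nrow(design))
  if (is.null(colnames(nuisance)))
    colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
  out <- cbind(design, nuisance)
  attr(out, "event_counts") <- attr(design, "event_counts")
  out
}

#' Voxelwise ordinary least squares GLM
#'
#' Fits `y_v = X b_v + e_v` independently at every voxel and reports betas and
#' residual variance.
#'
#' @param y Voxels x frames matrix (the orientation reconstruction produces),
#'   or a single series.
#' @param design Frames x p design matrix from [build_design()].
#' @return A `glm_result`: `betas` (voxels x p), `design`, `event_counts`,
#'   `resid_var` (per voxel, denominator `frames - p`), `df`.
#' @export
fit_glm <- function(y, design) {
  y <- if (is.matrix(y)) y else matrix(y, nrow = 1)
  X <- as.matrix(design)
  if (ncol(y) != nrow(X))
    stop_fnirsdot(sprintf("%d frames of data vs %d design rows", ncol(y), nrow(X)),
                  "shape_mismatch")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_fnirsdot(paste0("rank-deficient design; collinear column(s): ",
                         paste(dropped, collapse = ", ")), "rank_deficient")
  }
  B <- t(qr.coef(qx, t(y)))                     # voxels x p
  res <- y - B %*% t(X)
  df <- nrow(X) - ncol(X)
  structure(list(betas = B, design = X,
                 event_counts = attr(design, "event_counts"),
                 resid_var = rowSums(res^2) / max(df, 1L), df = df),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> %d voxels, %d regressor(s): %s; %d residual df\n",
              nrow(x$betas), ncol(x$betas),
              paste(colnames(x$betas), collapse = ", "), x$df))
  invisible(x)
}

#' Event-count-weighted average of betas over runs
#'
#' Runs differ in how many usable events each condition retains (trigger
#' rejection, early stops), so per-condition betas are combined as
#' `sum_r n_rc * b_rc / sum_r n_rc`. Conditions with zero events everywhere
#' are returned as `NA` and listed in the `missing` attribute.
#'
#' @param results List of `glm_result`s sharing a condition set.
#' @return Voxels x condition matrix of combined betas.
#' @export
weighted_average_betas <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L)
  conds <- names(results[[1]]$event_counts)
  for (r in results)
    if (!setequal(names(r$event_counts), conds))
      stop_fnirsdot("runs must share one condition set", "paradigm_invalid")
  nv <- nrow(results[[1]]$betas)
  out <- matrix(NA_real_, nv, length(conds), dimnames = list(NULL, conds))
  totals <- stats::setNames(numeric(length(conds)), conds)
  for (cn in conds) {
    acc <- numeric(nv); tot <- 0
    for (r in results) {
      n <- r$event_counts[[cn]]
      if (n > 0) { acc <- acc + n * r$betas[, cn]; tot <- tot + n }
    }
    totals[cn] <- tot
    if (tot > 0) out[, cn] <- acc / tot
  }
  if (all(totals == 0))
    stop_fnirsdot("zero events for every condition across all runs",
                  "paradigm_invalid")
  attr(out, "missing") <- conds[totals == 0]
  attr(out, "total_events") <- totals
  out
}
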