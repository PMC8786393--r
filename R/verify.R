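#' Sphere ROI at a channel's cortical sensitivity maximum
#'
#' Places the centroid of a sphere (default 2 cm diameter) at the maximum of
#' the channel's sensitivity volume restricted to the cortex mask — the
#' restriction keeps the center out of scalp/skull where sensitivity is
#' highest. Members are all voxels whose centers lie within `diameter_mm / 2`
#' of the center, intersected with the mask and, when given, the retained
#' voxel set. Argmax ties break to the first voxel in linear (column-major)
#' order.
#'
#' @param sensitivity 3D sensitivity array for one channel.
#' @param cortex_mask 3D logical array (gray matter by default upstream).
#' @param diameter_mm Sphere diameter, default 20 mm.
#' @param voxel_size_mm Isotropic voxel size.
#' @param good_vox Optional retained-voxel indices to intersect with.
#' @return A `sphere_roi`: `center` (linear voxel index), `members` (linear
#'   indices), `diameter_mm`.
#' @export
sphere_at_channel_max <- function(sensitivity, cortex_mask, diameter_mm = 20,
                                  voxel_size_mm = 1, good_vox = NULL) {
  d <- dim(sensitivity)
  stopifnot(identical(d, dim(cortex_mask)))
  mask <- as.logical(cortex_mask)
  if (!any(mask))
    stop_fnirsdot("empty cortex mask", "empty_model")
  s <- as.numeric(sensitivity)
  s[!mask] <- -Inf
  if (max(s) <= 0)
    stop_fnirsdot("sensitivity is zero everywhere in the cortex mask",
                  "empty_model")
  center <- which.max(s)
  cidx <- arrayInd(center, d)
  grid <- arrayInd(seq_len(prod(d)), d)
  dist2 <- ((grid[, 1] - cidx[1])^2 + (grid[, 2] - cidx[2])^2 +
            (grid[, 3] - cidx[3])^2) * voxel_size_mm^2
  members <- which(dist2 <= (diameter_mm / 2)^2 & mask)
  if (!is.null(good_vox)) members <- intersect(members, good_vox)
  if (!(center %in% members)) members <- sort(c(center, members))
  structure(list(center = center, members = members, diameter_mm = diameter_mm),
            class = "sphere_roi")
}

#' Mean time series over a sphere ROI
#'
#' Unweighted mean across member voxels per frame.
#'
#' @param x Retained-voxels x frames matrix (e.g. a `recon_result` chromophore).
#' @param roi A [sphere_at_channel_max()] ROI.
#' @param good_vox Retained-voxel indices labelling the rows of `x`.
#' @export
extract_mean_timeseries <- function(x, roi, good_vox) {
  rows <- match(roi$members, good_vox)
  rows <- rows[!is.na(rows)]
  if (length(rows) == 0L)
    stop_fnirsdot("ROI has no members among the retained voxels", "empty_model")
  colMeans(x[rows, , drop = FALSE])
}

#' Correlate a channel series with an image-extracted series
#'
#' Pearson correlation between the channel-based time series and the mean
#' image-reconstructed series from the channel's sphere; agreement above the
#' criterion (default 0.25) counts as a pass.
#'
#' @param channel_series,image_series Equal-length numeric series at the same
#'   rate.
#' @param criterion Pass threshold on r (strict `>`), default 0.25.
#' @return List with `r` and `pass`.
#' @export
correlate_channel_image <- function(channel_series, image_series,
                                    criterion = 0.25) {
  stopifnot(length(channel_series) == length(image_series))
  if (stats::sd(channel_series) == 0 || stats::sd(image_series) == 0)
    stop_fnirsdot("zero-variance series; correlation undefined", "degenerate_series")
  r <- stats::cor(channel_series, image_series)
  list(r = r, pass = r > criterion)
}

# Per-channel chromophore series from two-wavelength OD data: solves the same
# 2x2 extinction system used for images, so channel and image series share
# units up to pathlength scaling (irrelevant to correlation).
channel_chromophores <- function(rec, channel_rows, wavelengths_nm, table = NULL) {
  od <- lapply(seq_along(wavelengths_nm), function(i)
    matrix(rec$data[, channel_rows[i]], nrow = 1))
  spectroscopy_img(od, wavelengths_nm, table)
}

#' Centroid of the dominant activation cluster
#'
#' Thresholds the map at `frac` of its (masked) maximum, groups the
#' suprathreshold voxels into face-connected clusters (first-nearest-neighbor
#' connectivity, the NN1 convention of volumetric cluster tools), keeps the
#' cluster with the largest integrated value, and returns its center of mass.
#' For the smoothed, regularized maps diffuse optical reconstruction produces,
#' a raw argmax is not a stable location — the map around the true focus is a
#' broad plateau, and regression preprocessing leaves low-amplitude ripple
#' lobes elsewhere; mass-weighted clustering localizes the dominant focus
#' robustly.
#'
#' @param values Numeric vector over the model's retained voxels (e.g. one
#'   column of betas or a time-averaged chromophore map).
#' @param model A `sensitivity_model` (or any list with `good_vox`, `dim`,
#'   `voxel_size_mm`).
#' @param mask Optional 3D logical mask (e.g. cortex).
#' @param frac Threshold as a fraction of the masked maximum (default 0.5).
#' @return List with `index` (voxel nearest the centroid), `ijk` (fractional
#'   voxel coordinates), `mm` (coordinates relative to the volume center),
#'   and `cluster_size` (voxel count of the dominant cluster).
#' @export
activation_centroid <- function(values, model, mask = NULL, frac = 0.5) {
  stopifnot(length(values) == length(model$good_vox), frac > 0, frac <= 1)
  keep <- rep(TRUE, length(values))
  if (!is.null(mask)) keep <- as.logical(mask)[model$good_vox]
  if (!any(keep))
    stop_fnirsdot("mask excludes every retained voxel", "empty_model")
  v <- ifelse(keep, values, -Inf)
  thr <- frac * max(v)
  sel <- which(v >= thr & is.finite(v) & v > 0)
  if (length(sel) == 0L)
    stop_fnirsdot("no positive voxels above threshold", "empty_model")
  lin <- model$good_vox[sel]
  d <- model$dim
  # face-connected (NN1) components over the suprathreshold set
  inset <- integer(prod(d))
  inset[lin] <- seq_along(lin)
  comp <- integer(length(lin))
  ijk_all <- arrayInd(lin, d)
  ncomp <- 0L
  for (start in seq_along(lin)) {
    if (comp[start] > 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    comp[start] <- ncomp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      p <- ijk_all[cur, ]
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        q <- p
        q[ax] <- q[ax] + dd
        if (q[ax] < 1L || q[ax] > d[ax]) next
        nb <- inset[q[1] + (q[2] - 1L) * d[1] + (q[3] - 1L) * d[1] * d[2]]
        if (nb > 0L && comp[nb] == 0L) {
          comp[nb] <- ncomp
          queue <- c(queue, nb)
        }
      }
    }
  }
  mass <- vapply(seq_len(ncomp), function(k) sum(values[sel[comp == k]]),
                 numeric(1))
  main <- which.max(mass)
  pick <- comp == main
  w <- values[sel[pick]] / sum(values[sel[pick]])
  ijk <- colSums(ijk_all[pick, , drop = FALSE] * w)
  ctr <- (d + 1) / 2
  nearest <- sel[pick][which.min(rowSums(sweep(ijk_all[pick, , drop = FALSE],
                                               2, ijk)^2))]
  list(index = model$good_vox[nearest], ijk = ijk,
       mm = (ijk - ctr) * model$voxel_size_mm,
       cluster_size = sum(pick))
}

#' Verify a reconstruction against channel data
#'
#' For every usable channel (both wavelengths unpruned): build the sphere ROI
#' at the channel's cortex-restricted sensitivity maximum, extract the mean
#' reconstructed HbO2 and HbR series, convert the channel's two-wavelength OD
#' series to chromophores through the same extinction table, and correlate the
#' pairs. The per-channel sensitivity volume is the mean of the channel's
#' per-wavelength sensitivities.
#'
#' @param recon A `recon_result`.
#' @param rec The preprocessed recording the reconstruction used (same rate).
#' @param model The `sensitivity_model`.
#' @param cortex_mask 3D logical cortex mask (e.g. gray-matter label).
#' @param criterion Pass threshold on r, default 0.25.
#' @param diameter_mm Sphere diameter, default 20 mm.
#' @param table Extinction table override.
#' @return A `verification_report`: data frame `results` (channel,
#'   chromophore, r, pass) plus summary fields `n`, `n_pass`,
#'   `mean_r_passing`.
#' @export
verify_reconstruction <- function(recon, rec, model, cortex_mask,
                                  criterion = 0.25, diameter_mm = 20,
                                  table = NULL) {
  stopifnot(inherits(recon, "recon_result"), inherits(rec, "channel_recording"))
  ml <- model$measurements
  wl <- recon$wavelengths_nm
  chans <- unique(ml[, c("source", "detector")])
  rows <- list()
  for (i in seq_len(nrow(chans))) {
    pair_rows <- vapply(wl, function(w)
      which(ml$source == chans$source[i] & ml$detector == chans$detector[i] &
            ml$wavelength_nm == w)[1], integer(1))
    if (anyNA(pair_rows) || !all(rec$good_meas[pair_rows])) next
    sens <- embed_to_volume(colMeans(model$A[pair_rows, , drop = FALSE]), model)
    roi <- sphere_at_channel_max(sens, cortex_mask, diameter_mm,
                                 model$voxel_size_mm, model$good_vox)
    ch <- channel_chromophores(rec, pair_rows, wl, table)
    for (chrom in c("hbo", "hbr")) {
      img <- extract_mean_timeseries(recon[[chrom]], roi, recon$good_vox)
      cc <- correlate_channel_image(as.numeric(ch[[chrom]]), img, criterion)
      rows[[length(rows) + 1L]] <- data.frame(
        source = chans$source[i], detector = chans$detector[i],
        chromophore = chrom, r = cc$r, pass = cc$pass)
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, criterion = criterion,
                 n = nrow(results), n_pass = sum(results$pass),
                 mean_r_passing = mean(results$r[results$pass])),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification_report> %d/%d correlations > %g (mean r of passing subset: %.3f)\n",
              x$n_pass, x$n, x$criterion, x$mean_r_passing))
  invisible(x)
}

#' Plot paired channel and image time series
#'
#' Base-graphics overlay of a channel chromophore series and the matching
#' sphere-mean image series.
#'
#' @param channel_series,image_series Numeric series.
#' @param fs Sampling rate for the time axis.
#' @param main Plot title.
#' @export
plot_channel_image_pair <- function(channel_series, image_series, fs = 1,
                                    main = "channel vs image") {
  t <- seq_along(channel_series) / fs
  graphics::plot(t, channel_series, type = "l", col = "black",
                 xlab = "time (s)", ylab = "signal", main = main)
  graphics::lines(t, image_series, col = "red")
  graphics::legend("topright", c("channel", "image"), col = c("black", "red"),
                   lty = 1, bty = "n")
  invisible(NULL)
}
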