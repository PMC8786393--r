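#' Measurement list constructor
#'
#' One row per measurement (a source-detector pair at one wavelength), in the
#' order that the rows of the sensitivity matrix and the columns of channel
#' data follow.
#'
#' @param source,detector 1-based optode indices.
#' @param wavelength_nm Wavelength in nm (e.g. 690/830 or 760/850).
#' @param sep2d_mm,sep3d_mm Source-detector separations (optional).
#' @param good Logical good-measurement flag.
#' @export
measurement_list <- function(source, detector, wavelength_nm,
                             sep2d_mm = NA_real_, sep3d_mm = NA_real_,
                             good = TRUE) {
  stopifnot(all(source >= 1), all(detector >= 1))
  data.frame(source = as.integer(source), detector = as.integer(detector),
             wavelength_nm = as.numeric(wavelength_nm),
             sep2d_mm = sep2d_mm, sep3d_mm = sep3d_mm, good = good)
}

#' Vectorize per-measurement sensitivity volumes into an A matrix
#'
#' Stacks each measurement's 3D sensitivity volume into one row of a 2D matrix
#' `A` (measurements x voxels), keeping only voxels whose sensitivity exceeds
#' `threshold_frac` of the global maximum over the combined volumes for at
#' least one measurement. The retained-voxel index set (`good_vox`) maps the
#' columns of `A` back into the flattened full volume; flattening follows R's
#' native column-major order over (x, y, z), and indices are 1-based
#' throughout, including on export. Dropping sub-threshold voxels typically
#' shrinks the model by a factor of 5-10.
#'
#' @param volumes List of 3D arrays (one per measurement, identical shape),
#'   or a 4D array with measurement as the 4th dimension.
#' @param threshold_frac Retention threshold as a fraction of the global
#'   maximum; default 0.01. Comparison is strict (`>`).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param measurements Optional [measurement_list()] ordered as `volumes`.
#' @return An object of class `sensitivity_model`: `A`, `good_vox`, `dim`
#'   (volume shape), `voxel_size_mm`, `threshold_used`, `measurements`.
#' @export
vectorize_sensitivity <- function(volumes, threshold_frac = 0.01,
                                  voxel_size_mm = 1, measurements = NULL) {
  stopifnot(threshold_frac > 0, threshold_frac < 1)
  if (is.array(volumes) && length(dim(volumes)) == 4L) {
    volumes <- lapply(seq_len(dim(volumes)[4]), function(i) volumes[, , , i])
  }
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  shp <- dim(volumes[[1]])
  stopifnot(length(shp) == 3L)
  for (v in volumes) {
    if (!identical(dim(v), shp))
      stop_fnirsdot("all sensitivity volumes must share one shape", "shape_mismatch")
  }
  flat <- vapply(volumes, as.numeric, numeric(prod(shp)))  # voxels x meas
  M <- max(flat)
  if (M <= 0)
    stop_fnirsdot("all sensitivity volumes are zero; empty model", "empty_model")
  keep <- rowSums(flat > threshold_frac * M) > 0L
  good_vox <- which(keep)
  A <- t(flat[good_vox, , drop = FALSE])                   # meas x retained voxels
  if (!is.null(measurements)) stopifnot(nrow(measurements) == nrow(A))
  structure(list(A = A, good_vox = good_vox, dim = shp,
                 voxel_size_mm = voxel_size_mm,
                 threshold_used = threshold_frac,
                 measurements = measurements),
            class = "sensitivity_model")
}

#' @export
print.sensitivity_model <- function(x, ...) {
  cat(sprintf("<sensitivity_model> %d measurements x %d retained voxels (of %d; %.1fx reduction), threshold %g of max\n",
              nrow(x$A), ncol(x$A), prod(x$dim), prod(x$dim) / ncol(x$A),
              x$threshold_used))
  invisible(x)
}

#' Embed retained-voxel values back into the full volume
#'
#' Inverse of the restriction used by [vectorize_sensitivity()]: values over
#' `good_vox` are scattered into a full 3D array, zeros elsewhere.
#'
#' @param values Numeric vector with one value per retained voxel.
#' @param model A `sensitivity_model` (or any list with `good_vox` and `dim`).
#' @export
embed_to_volume <- function(values, model) {
  if (length(values) != length(model$good_vox))
    stop_fnirsdot(sprintf("got %d values for %d retained voxels",
                          length(values), length(model$good_vox)),
                  "index_error")
  out <- numeric(prod(model$dim))
  out[model$good_vox] <- values
  array(out, dim = model$dim)
}

#' Restrict a full volume to the retained voxels
#' @param volume 3D array with the model's shape.
#' @inheritParams embed_to_volume
#' @export
restrict_to_good_vox <- function(volume, model) {
  if (!identical(dim(volume), model$dim))
    stop_fnirsdot("volume shape does not match the model", "shape_mismatch")
  as.numeric(volume)[model$good_vox]
}

#' Read per-measurement sensitivity volumes from NIFTI files
#'
#' All files must agree in shape and affine (to 1e-6); the common geometry is
#' returned alongside the list of arrays.
#'
#' @param paths Character vector of NIFTI-1 file paths, in measurement order.
#' @return List with `volumes`, `voxel_size_mm`, `affine`.
#' @export
read_nifti_sensitivity <- function(paths) {
  imgs <- lapply(paths, RNifti::readNifti)
  shp <- dim(imgs[[1]])
  aff <- RNifti::xform(imgs[[1]])
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), shp))
      stop_fnirsdot(sprintf("'%s' shape differs from '%s'", paths[i], paths[1]),
                    "shape_mismatch")
    if (max(abs(RNifti::xform(imgs[[i]]) - aff)) > 1e-6)
      stop_fnirsdot(sprintf("'%s' affine differs from '%s'", paths[i], paths[1]),
                    "affine_mismatch")
  }
  list(volumes = lapply(imgs, function(im) array(as.numeric(im), dim = shp)),
       voxel_size_mm = RNifti::pixdim(imgs[[1]])[1],
       affine = aff)
}

#' Write a 3D volume as NIFTI-1
#'
#' @param volume 3D array.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param voxel_size_mm Isotropic voxel size.
#' @export
write_nifti <- function(volume, path, voxel_size_mm = 1) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}
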