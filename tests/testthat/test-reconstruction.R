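# Independent oracle: the voxel-space Tikhonov formula written out directly.
voxel_space_inverse <- function(A, lambda1, lambda2) {
  l <- sqrt(colSums(A^2) + lambda2)
  At <- sweep(A, 2, l, `/`)
  diag(1 / l) %*% solve(crossprod(At) + lambda1 * diag(ncol(A)), t(At))
}

test_that("identity sensitivity with vanishing penalties inverts to identity", {
  op <- invert_sensitivity(diag(4), lambda1 = 1e-12, lambda2 = 0)
  expect_equal(op$W, diag(4), tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(invert_sensitivity(matrix(numeric(0), 0, 0)),
               class = "empty_model")
})

test_that("measurement- and voxel-space forms agree (push-through identity)", {
  set.seed(21)
  for (i in 1:30) {
    nm <- sample(2:6, 1); nv <- sample(2:9, 1)
    A <- matrix(rexp(nm * nv), nm, nv)
    W1 <- invert_sensitivity(A, 0.01, 0.1, force_form = "measurement")$W
    W2 <- invert_sensitivity(A, 0.01, 0.1, force_form = "voxel")$W
    expect_lt(max(abs(W1 - W2)), 1e-8)
    # and both match the written-out voxel-space oracle
    expect_lt(max(abs(W2 - voxel_space_inverse(A, 0.01, 0.1))), 1e-8)
  }
})

test_that("lambda2 = 0 reduces the penalty to sqrt(diag(AtA))", {
  set.seed(22)
  A <- matrix(runif(12, 0.1, 1), 3, 4)
  W <- invert_sensitivity(A, 0.01, 0)$W
  l <- sqrt(colSums(A^2))
  At <- sweep(A, 2, l, `/`)
  Woracle <- diag(1 / l) %*% t(At) %*% solve(tcrossprod(At) + 0.01 * diag(3))
  expect_lt(max(abs(W - Woracle)), 1e-10)
})

test_that("rank-deficient unregularized systems fail informatively", {
  A <- rbind(c(1, 2), c(2, 4))  # rank 1
  expect_error(invert_sensitivity(A, lambda1 = 0, lambda2 = 0),
               class = "singular_system")
})

test_that("reconstruction is linear and localizes a sparse source", {
  set.seed(23)
  A <- matrix(rexp(8 * 30), 8, 30)
  op <- invert_sensitivity(A, 1e-6, 0.1)
  expect_equal(reconstruct_img(op, numeric(8)), matrix(0, 30, 1),
               ignore_attr = TRUE)
  y <- rnorm(8)
  expect_equal(reconstruct_img(op, 3 * y), 3 * reconstruct_img(op, y))
  expect_error(reconstruct_img(op, numeric(5)), class = "shape_mismatch")

  # forward-project a point source, invert, peak at its support
  x0 <- numeric(30); x0[17] <- 1
  xr <- reconstruct_img(op, as.numeric(A %*% x0))
  expect_equal(which.max(abs(xr)), 17L)
})

test_that("solution norm is non-increasing in lambda1", {
  set.seed(24)
  A <- matrix(rexp(6 * 40), 6, 40)
  y <- rnorm(6)
  norms <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1, 1, 10), function(l1)
    sqrt(sum(reconstruct_img(invert_sensitivity(A, l1, 0.1), y)^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("spatially variant regularization boosts deep voxels", {
  # one measurement, a shallow voxel (sensitivity 1) and a deep one (0.2)
  A <- matrix(c(1, 0.2), 1, 2)
  ratio_of <- function(op) {
    x <- reconstruct_img(op, 1)
    x[2] / x[1]
  }
  r_variant <- ratio_of(invert_sensitivity(A, 0.01, 0.1))
  r_identity <- ratio_of(invert_sensitivity(A, 0.01, 0.1,
                                            spatially_variant = FALSE))
  expect_gt(r_variant, r_identity)
  # the depth boost is strongest at lambda2 = 0 and decays as lambda2 grows
  r_l2 <- vapply(c(0, 0.05, 0.5, 5), function(l2)
    ratio_of(invert_sensitivity(A, 0.01, l2)), numeric(1))
  expect_true(all(diff(r_l2) < 0))
  expect_gt(r_l2[1], 1)
})

test_that("gaussian smoothing matches a brute-force kernel and conserves mass", {
  model <- list(good_vox = seq_len(15^3), dim = c(15L, 15L, 15L),
                voxel_size_mm = 2)
  x <- numeric(15^3)
  center <- cbind(8, 8, 8)
  x[8 + 7 * 15 + 7 * 225] <- 1
  sm <- smooth_images(matrix(x), fwhm_mm = 6, model)
  # independent oracle: evaluate the separable discrete kernel directly
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 2
  half <- max(1, ceiling(4 * sigma))
  k1 <- exp(-((-half):half)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  oracle <- numeric(15^3)
  idx <- arrayInd(seq_len(15^3), c(15, 15, 15))
  off <- sweep(idx, 2, c(8, 8, 8))
  inside <- abs(off[, 1]) <= half & abs(off[, 2]) <= half & abs(off[, 3]) <= half
  oracle[inside] <- k1[off[inside, 1] + half + 1] * k1[off[inside, 2] + half + 1] *
    k1[off[inside, 3] + half + 1]
  expect_lt(max(abs(sm[, 1] - oracle)), 1e-6)
  expect_equal(sum(sm), 1, tolerance = 1e-8)  # away from boundary

  # FWHM far below the voxel size approaches the identity
  tiny <- suppressWarnings(smooth_images(matrix(x), fwhm_mm = 0.2, model))
  expect_equal(suppressWarnings(max(abs(tiny - x))), 0, tolerance = 0.02)
  expect_warning(smooth_images(matrix(x), fwhm_mm = 0.2, model), "FWHM")
  expect_error(smooth_images(matrix(x), fwhm_mm = -1, model),
               class = "parameter_error")
})

test_that("spectroscopy round-trips hemoglobin through absorption", {
  z <- matrix(0, 4, 3)
  out0 <- spectroscopy_img(list(z, z))
  expect_equal(out0$hbo, z)
  expect_equal(out0$hbr, z)

  set.seed(25)
  hbo <- matrix(rnorm(12), 4, 3)
  hbr <- matrix(rnorm(12), 4, 3)
  mu <- forward_spectroscopy(hbo, hbr, c(690, 830))
  back <- spectroscopy_img(mu, c(690, 830))
  expect_lt(max(abs(back$hbo - hbo)), 1e-10)
  expect_lt(max(abs(back$hbr - hbr)), 1e-10)
  expect_equal(back$hbt, back$hbo + back$hbr)

  # known single-point forward/backward at (1, -0.3) uM
  mu1 <- forward_spectroscopy(matrix(1), matrix(-0.3), c(760, 850))
  b1 <- spectroscopy_img(mu1, c(760, 850))
  expect_equal(as.numeric(b1$hbo), 1, tolerance = 1e-10)
  expect_equal(as.numeric(b1$hbr), -0.3, tolerance = 1e-10)

  expect_error(extinction_coefficients(c(690, 999)), class = "parameter_error")
  same <- extinction_coefficients(c(690, 830))
  expect_true(attr(same, "kappa") > 1)
  degenerate <- data.frame(wavelength_nm = c(690, 830),
                           HbO2 = c(1, 2), HbR = c(2, 4))
  expect_error(spectroscopy_img(list(matrix(1), matrix(1)), c(690, 830),
                                table = degenerate),
               class = "singular_system")
})

test_that("smoothing folded into the operator equals smoothing the images", {
  phantom <- generate_phantom_head(phantom_spec(shape = c(20, 20, 20),
                                                r_white_mm = 8, r_gray_mm = 12,
                                                r_csf_mm = 14, r_head_mm = 18))
  probe <- probe_layout(phantom$spec, n_sources = 4)
  vols <- generate_sensitivity(phantom, probe)
  model <- vectorize_sensitivity(vols, 0.01, phantom$voxel_size_mm,
                                 probe$measurements)
  op <- invert_sensitivity(model$A, 0.01, 0.1)
  set.seed(26)
  y <- matrix(rnorm(nrow(model$A) * 5), nrow(model$A), 5)
  x <- reconstruct_img(op, y)
  a <- smooth_images(x, 6, model)
  op$W <- smooth_images(op$W, 6, model)
  b <- reconstruct_img(op, y)
  expect_lt(max(abs(a - b)), 1e-10)
})
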