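test_that("phantom layer volumes match the analytic sphere shells", {
  spec <- phantom_spec()
  ph <- generate_phantom_head(spec)
  counts <- table(factor(ph$labels, levels = 0:4))
  shell <- function(r1, r0 = 0) 4 / 3 * pi * (r1^3 - r0^3) / spec$voxel_size_mm^3
  expected <- c(shell(spec$r_head_mm, spec$r_csf_mm),
                shell(spec$r_csf_mm, spec$r_gray_mm),
                shell(spec$r_gray_mm, spec$r_white_mm),
                shell(spec$r_white_mm))
  for (k in 1:4)
    expect_equal(as.numeric(counts[k + 1]), expected[k], tolerance = 0.10)

  # determinism and degenerate input
  expect_identical(ph$labels, generate_phantom_head(spec)$labels)
  expect_error(generate_phantom_head(phantom_spec(shape = c(2, 2, 2),
                                                  voxel_size_mm = 0.01,
                                                  r_white_mm = 1e-4,
                                                  r_gray_mm = 2e-4,
                                                  r_csf_mm = 3e-4,
                                                  r_head_mm = 4e-4)),
               class = "empty_model")
})

test_that("sensitivity bananas are tissue-masked with an interior peak", {
  spec <- phantom_spec()
  ph <- generate_phantom_head(spec)
  probe <- probe_layout(spec)
  vols <- generate_sensitivity(ph, probe)
  expect_length(vols, nrow(probe$measurements))
  for (v in vols[1:4]) {
    expect_true(all(v >= 0))
    expect_equal(max(v), 1)
    expect_true(all(v[ph$labels == 0] == 0))
  }
  # argmax sits near the source-detector midpoint, inside the head
  xyz <- fnirsdot:::voxel_coords_mm(spec$shape, spec$voxel_size_mm)
  mid <- (probe$sources[1, ] + probe$detectors[1, ]) / 2
  pk <- xyz[which.max(vols[[1]]), ]
  expect_lt(sqrt(sum((pk - mid)^2)), 2 * spec$voxel_size_mm + 1e-9)
  expect_lt(sqrt(sum(pk^2)), spec$r_head_mm)

  # zero separation degenerates to a single blob under the optode
  probe0 <- probe
  probe0$detectors <- probe0$sources
  v0 <- generate_sensitivity(ph, probe0)[[1]]
  pk0 <- xyz[which.max(v0), ]
  s1 <- probe$sources[1, ]
  # peak at the tissue voxel nearest the optode (which sits on the scalp)
  expect_lt(sqrt(sum((pk0 - s1)^2)), 2 * spec$voxel_size_mm + 1e-9)
})

test_that("synthetic caps are rigid copies plus recorded slips", {
  tpl <- synthetic_template_cap()
  clean <- generate_caps(tpl, n = 3, noise_sd_cm = 0, seed = 5)
  for (cp in clean)
    expect_lt(rmsd(kabsch_align(cp, tpl)$aligned, tpl), 1e-8)

  slipped <- generate_caps(tpl, n = 3, noise_sd_cm = 0, n_outlier_points = 2,
                           outlier_shift_cm = 15, seed = 5)
  truth <- attr(slipped, "outliers")
  for (i in seq_along(slipped)) {
    al <- kabsch_align(slipped[[i]], tpl)
    far <- which(al$distances > 5)
    expect_setequal(far, truth[[i]])
  }

  # seeded repeatability
  again <- generate_caps(tpl, n = 3, noise_sd_cm = 0.3, n_outlier_points = 1,
                         seed = 9)
  again2 <- generate_caps(tpl, n = 3, noise_sd_cm = 0.3, n_outlier_points = 1,
                          seed = 9)
  expect_identical(lapply(again, `[[`, "points"),
                   lapply(again2, `[[`, "points"))
})

small_fixture <- function() {
  spec <- phantom_spec(shape = c(24, 24, 24), r_white_mm = 12, r_gray_mm = 16,
                       r_csf_mm = 18, r_head_mm = 22)
  ph <- generate_phantom_head(spec)
  probe <- probe_layout(spec, n_sources = 4)
  vols <- generate_sensitivity(ph, probe)
  model <- vectorize_sensitivity(vols, 0.01, spec$voxel_size_mm,
                                 probe$measurements)
  list(spec = spec, phantom = ph, probe = probe, model = model)
}

test_that("channel data with no activation and no noise are constant", {
  fx <- small_fixture()
  par <- data.frame(onset_s = c(5, 15), condition = c("A", "A"))
  sim <- generate_channel_data(fx$model, par,
                               activation = list(center = fx$model$good_vox[1],
                                                 hbo = c(A = 0), hbr = c(A = 0)),
                               fs = 10, duration_s = 30, white_sd = 0,
                               physio_amp = 0, seed = 1)
  expect_equal(max(sim$recording$data) - min(sim$recording$data), 0)
  expect_equal(sim$recording$unit, "intensity")
  expect_true(all(abs(sim$truth$clean_od) == 0))
})

test_that("forward simulation then inversion peaks at the injected voxel", {
  spec <- phantom_spec()
  phantom <- generate_phantom_head(spec)
  probe <- probe_layout(spec)
  vols <- generate_sensitivity(phantom, probe)
  model <- vectorize_sensitivity(vols, 0.01, spec$voxel_size_mm,
                                 probe$measurements)
  cortex <- phantom$labels == 3L
  ctr <- cortical_peak_voxel(model, cortex, 1L)
  par <- data.frame(onset_s = c(5, 15), condition = c("A", "A"))
  sim <- generate_channel_data(model, par,
                               activation = list(center = ctr, sigma_mm = 4,
                                                 hbo = c(A = 1), hbr = c(A = -0.3)),
                               fs = 10, duration_s = 40, white_sd = 0,
                               physio_amp = 0, seed = 1)
  rec <- intensity_to_od(sim$recording)
  recon <- reconstruct_recording(model, rec)
  # OD conversion centers each channel, so localize on the RMS response map;
  # the regularized inverse spreads a point source into a plateau, so the
  # dominant-cluster centroid is the location estimate
  rms_map <- sqrt(rowMeans(recon$hbo^2))
  com <- activation_centroid(rms_map, model, cortex)
  ctr_mm <- (arrayInd(ctr, model$dim) - (model$dim + 1) / 2) * spec$voxel_size_mm
  off <- sqrt(sum((com$mm - ctr_mm)^2))
  expect_lte(off, 2 * spec$voxel_size_mm)
  fx <- small_fixture()
  ctr <- cortical_peak_voxel(fx$model, fx$phantom$labels == 3L, 1L)

  # seeded repeatability of the noisy path
  s1 <- generate_channel_data(fx$model, par,
                              activation = list(center = ctr, hbo = c(A = 1),
                                                hbr = c(A = -0.3)),
                              fs = 10, duration_s = 30, seed = 4)
  s2 <- generate_channel_data(fx$model, par,
                              activation = list(center = ctr, hbo = c(A = 1),
                                                hbr = c(A = -0.3)),
                              fs = 10, duration_s = 30, seed = 4)
  expect_identical(s1$recording$data, s2$recording$data)
  # generators restore the global RNG state
  set.seed(77); before <- rnorm(1)
  set.seed(77)
  invisible(generate_channel_data(fx$model, par,
                                  activation = list(center = ctr, hbo = c(A = 1),
                                                    hbr = c(A = -0.3)),
                                  fs = 10, duration_s = 30, seed = 4))
  expect_identical(rnorm(1), before)
})
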