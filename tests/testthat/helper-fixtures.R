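# Shared fixtures, all built in code.

# A minimal 3-point layout: 1 landmark, 1 source, 1 detector.
tiny_layout <- function(unit = "cm") cap_layout(1, 1, 1, unit = unit)

# Random proper rotation via QR of a Gaussian matrix (det forced to +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(points, R, shift) {
  sweep(points %*% t(R), 2, shift, `+`)
}

# Rotation about z by `deg` degrees.
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Small hand-checkable sensitivity model: 2 measurements x 4 voxels embedded
# in a 2x2x1 volume.
tiny_model <- function() {
  v1 <- array(c(1, 0.5, 0.001, 0), dim = c(2, 2, 1))
  v2 <- array(c(0, 0.02, 0.001, 0), dim = c(2, 2, 1))
  vectorize_sensitivity(list(v1, v2), threshold_frac = 0.01, voxel_size_mm = 1,
                        measurements = measurement_list(c(1, 1), c(1, 1),
                                                        c(690, 830)))
}

# A recording with a known sine composition for filter tests.
sine_recording <- function(fs = 10, duration = 300, freqs = 0.1, amps = 1,
                           dc = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- dc + rowSums(vapply(seq_along(freqs),
                           function(i) amps[i] * sin(2 * pi * freqs[i] * t),
                           numeric(length(t))))
  channel_recording(cbind(x, x), fs,
                    measurement_list(c(1, 1), c(1, 1), c(690, 830)),
                    unit = "od")
}

# FFT amplitude of a series at frequency f.
fft_amp <- function(x, fs, f) {
  n <- length(x)
  fr <- (0:(n - 1)) * fs / n
  2 * abs(stats::fft(x)[which.min(abs(fr - f))]) / n
}
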