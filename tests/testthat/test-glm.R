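test_that("gamma HRF has the documented shape", {
  h <- gamma_hrf(fs = 25)
  expect_length(h, 400L)          # 16 s at 25 Hz
  expect_equal(max(h), 1)
  expect_error(gamma_hrf(25, dispersion_response = 0), class = "parameter_error")

  # dense-grid argmax oracle for the peak time
  tgrid <- seq(0, 16, by = 1e-4)
  dense <- dgamma(tgrid, shape = 4, scale = 1) - dgamma(tgrid, 15, scale = 1) / 6
  t_oracle <- tgrid[which.max(dense)]
  t_kernel <- (which.max(h) - 1) / 25
  expect_lt(abs(t_kernel - t_oracle), 1 / 25)
  expect_lt(abs(t_oracle - 3), 0.05)  # mode of the response gamma: delay - dispersion
})

test_that("design regressors are HRF convolutions of the event train", {
  fs <- 25; n <- 1000
  h <- gamma_hrf(fs)
  # single impulse event: regressor is the shifted kernel
  X <- build_design(data.frame(onset_s = 4, condition = "A"), h, fs, n,
                    event_extent_s = 0, intercept = FALSE)
  on <- 1 + 4 * fs
  expect_equal(X[on:(on + 399), "A"], as.numeric(h), ignore_attr = TRUE)
  expect_true(all(X[1:(on - 1), "A"] == 0))

  # two non-overlapping events superpose
  X2 <- build_design(data.frame(onset_s = c(2, 25), condition = c("A", "A")),
                     h, fs, n, event_extent_s = 0, intercept = FALSE)
  X2a <- build_design(data.frame(onset_s = 2, condition = "A"), h, fs, n, 0,
                      intercept = FALSE)
  X2b <- build_design(data.frame(onset_s = 25, condition = "A"), h, fs, n, 0,
                      intercept = FALSE)
  expect_equal(X2[, "A"], X2a[, "A"] + X2b[, "A"], ignore_attr = TRUE)

  # boxcar support: 4.5 s at 25 Hz = 112 frames of the indicator before the HRF
  Xb <- build_design(data.frame(onset_s = 0, condition = "A"), c(1), fs, n,
                     event_extent_s = 4.5, intercept = FALSE)
  expect_equal(sum(Xb[, "A"]), round(4.5 * fs))

  expect_equal(attr(X2, "event_counts"), c(A = 2L))
  expect_error(build_design(data.frame(onset_s = numeric(0),
                                       condition = character(0)), h, fs, n),
               class = "paradigm_invalid")
  expect_error(build_design(data.frame(onset_s = 50, condition = "A"), h, fs, n),
               class = "paradigm_invalid")
})

test_that("condition maps collapse conditions onto shared regressors", {
  h <- gamma_hrf(10)
  par <- data.frame(onset_s = c(1, 5, 9), condition = c("a1", "a2", "b"))
  X <- build_design(par, h, 10, 300, condition_map = c(a1 = "a", a2 = "a", b = "b"),
                    intercept = FALSE)
  expect_equal(colnames(X), c("a", "b"))
  expect_equal(attr(X, "event_counts"), c(a = 2L, b = 1L))
})

test_that("design regressors vanish before events and decay after the window", {
  fs <- 25
  h <- gamma_hrf(fs)
  X <- build_design(data.frame(onset_s = 10, condition = "A"), h, fs, 35 * fs,
                    event_extent_s = 0, intercept = FALSE)
  expect_true(all(X[seq_len((10 - 1) * fs), "A"] == 0))
  # support ends 16 s (kernel length) after onset, within the 20 s window
  expect_true(all(X[((10 + 16) * fs + 2):(35 * fs), "A"] == 0))
})

test_that("ordinary least squares recovers exact and orthonormal solutions", {
  set.seed(31)
  X <- cbind(intercept = 1, A = rnorm(50), B = rnorm(50))
  attr(X, "event_counts") <- c(A = 1L, B = 1L)
  B0 <- rbind(c(0.5, 2, -1), c(0, 1, 4))
  y <- B0 %*% t(X)
  fit <- fit_glm(y, X)
  expect_equal(fit$betas, B0, tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(max(fit$resid_var), 1e-20)

  Q <- qr.Q(qr(matrix(rnorm(60 * 2), 60, 2)))
  colnames(Q) <- c("A", "B")
  y2 <- matrix(rnorm(60), 1, 60)
  fit2 <- fit_glm(y2, Q)
  expect_equal(as.numeric(fit2$betas), as.numeric(y2 %*% Q), tolerance = 1e-10)

  Xbad <- cbind(a = rnorm(20), b = 1:20, c = 2 * (1:20))
  err <- expect_error(fit_glm(matrix(rnorm(20), 1, 20), Xbad),
                      class = "rank_deficient")
  expect_match(conditionMessage(err), "c")
  expect_error(fit_glm(matrix(0, 1, 10), X), class = "shape_mismatch")
})

test_that("beta estimates are unbiased under gaussian noise", {
  set.seed(32)
  fs <- 5; n <- 200
  X <- build_design(data.frame(onset_s = c(5, 20), condition = c("A", "B")),
                    gamma_hrf(fs), fs, n)
  b0 <- c(0.2, 3, 1.5)
  mu <- as.numeric(X %*% b0)
  sims <- t(vapply(1:200, function(i) {
    fit_glm(matrix(mu + rnorm(n, 0, 1), 1), X)$betas[1, ]
  }, numeric(3)))
  se <- apply(sims, 2, sd) / sqrt(nrow(sims))
  expect_true(all(abs(colMeans(sims) - b0) < 2.5 * se + 1e-9))
})

test_that("betas combine across runs weighted by event counts", {
  mk <- function(betas, counts) {
    structure(list(betas = matrix(betas, 1, length(betas),
                                  dimnames = list(NULL, names(counts))),
                   event_counts = counts), class = "glm_result")
  }
  # runs with (count, beta) = (3, 0) and (1, 4) -> 1.0
  out <- weighted_average_betas(list(mk(0, c(A = 3L)), mk(4, c(A = 1L))))
  expect_equal(as.numeric(out[, "A"]), 1)

  # equal counts reduce to the simple mean
  out2 <- weighted_average_betas(list(mk(c(1, 2), c(A = 2L, B = 2L)),
                                      mk(c(3, 6), c(A = 2L, B = 2L))))
  expect_equal(as.numeric(out2), c(2, 4))

  # single run is the identity
  out3 <- weighted_average_betas(list(mk(c(5, 7), c(A = 1L, B = 3L))))
  expect_equal(as.numeric(out3), c(5, 7))

  # conditions with zero events everywhere are flagged missing
  out4 <- weighted_average_betas(list(mk(c(1, 9), c(A = 2L, B = 0L)),
                                      mk(c(3, 9), c(A = 2L, B = 0L))))
  expect_true(is.na(out4[, "B"]))
  expect_equal(attr(out4, "missing"), "B")
  expect_error(weighted_average_betas(list(mk(1, c(A = 0L)))),
               class = "paradigm_invalid")
})

test_that("design filtering and resampling track the data operators", {
  fs <- 50; n <- fs * 60
  X <- build_design(data.frame(onset_s = c(5, 25), condition = c("A", "B")),
                    gamma_hrf(fs), fs, n, event_extent_s = 4.5)
  Xf <- filter_design(X, fs)
  expect_equal(Xf[, "intercept"], rep(1, n), ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(Xf[, "A"], X[, "A"])))
  expect_equal(attr(Xf, "event_counts"), attr(X, "event_counts"))
  Xr <- resample_design(Xf, n / 2)
  expect_equal(nrow(Xr), n / 2)
  expect_equal(attr(Xr, "event_counts"), attr(X, "event_counts"))
  # the same operator applied to a data channel built from the regressor
  rec <- channel_recording(cbind(X[, "A"], X[, "A"]), fs,
                           measurement_list(c(1, 1), c(1, 1), c(690, 830)),
                           unit = "od")
  rec <- resample_recording(bandpass(rec), 25)
  expect_lt(max(abs(rec$data[, 1] - Xr[, "A"])), 1e-8)
})
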