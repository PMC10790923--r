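test_that("mBLL inversion solves the two-wavelength system", {
  ext <- extinction_coefficients()
  z <- mbll_inverse(c(0, 0), separation = 3, dpf = 6, extinction = ext)
  expect_equal(z$hbo, 0)
  expect_equal(z$hbr, 0)

  od <- mbll_forward(hbo = 1, hbr = 0, separation = 3, dpf = 6,
                     extinction = ext)
  back <- mbll_inverse(od, separation = 3, dpf = 6, extinction = ext)
  expect_equal(back$hbo, 1, tolerance = 1e-10)
  expect_equal(back$hbr, 0, tolerance = 1e-10)

  # identity coefficients and unit pathlength: concentrations equal OD
  eye <- diag(2); dimnames(eye) <- list(c("761", "847"), c("hbo", "hbr"))
  id <- mbll_inverse(c(0.3, -0.1), separation = 1, dpf = 1, extinction = eye)
  expect_equal(id$hbo, 0.3)
  expect_equal(id$hbr, -0.1)

  sing <- matrix(c(1, 2, 2, 4), 2)
  expect_error(mbll_inverse(c(1, 1), 3, 6, sing), "singular")
  expect_error(mbll_inverse(matrix(0, 3, 4), 3, 6, ext), "2 wavelengths")
  expect_error(mbll_forward(1, 0, separation = -1), "separation")
  expect_error(extinction_coefficients(c(700, 900)), "tabulated")
})

test_that("Chebyshev band-pass rejects DC and the cardiac band", {
  const <- rep(2.5, 3000)
  expect_lt(max(abs(chebyshev_bandpass(const))), 1e-6 * 2.5)

  t <- seq(0, 1200, by = 0.1)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  pass <- chebyshev_bandpass(sin(2 * pi * 0.05 * t))
  amp_pass <- max(abs(pass[mid]))
  stop1 <- chebyshev_bandpass(sin(2 * pi * 1 * t))
  amp_stop <- max(abs(stop1[mid]))
  expect_gte(amp_pass, 0.89)  # 0.5 dB design ripple, squared by filtfilt
  expect_lte(amp_pass, 1.0 + 1e-6)
  expect_lt(amp_stop, 0.01)   # >= 40 dB at 1 Hz

  # measured passband gain matches the design frequency response |H|^2
  cf <- signal::cheby1(3, 0.5, c(0.01, 0.09) / 5, type = "pass")
  H <- signal::freqz(cf, n = 8192, Fs = 10)
  h2 <- abs(H$h[which.min(abs(H$f - 0.05))])^2
  expect_equal(amp_pass, h2, tolerance = 0.01)

  expect_error(chebyshev_bandpass(rnorm(100), band = c(0.09, 0.01)),
               "increasing")
  expect_error(chebyshev_bandpass(rnorm(100), band = c(0.01, 6)), "Nyquist")
})

test_that("filtering twice composes like the squared transfer function", {
  t <- seq(0, 2000, by = 0.1)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  for (f in c(0.03, 0.05, 0.08)) {
    once <- chebyshev_bandpass(sin(2 * pi * f * t))
    twice <- chebyshev_bandpass(once)
    a1 <- max(abs(once[mid]))
    a2 <- max(abs(twice[mid]))
    expect_equal(a2, a1^2, tolerance = 0.02)
  }
})

test_that("motion segments need agreement between accelerometer and fNIRS", {
  set.seed(11)
  n_s <- 60
  flat_accel <- matrix(rnorm(3 * n_s * 512, 0, 1e-4), 3) + c(0, 0, 1)
  noisy_fnirs <- rnorm(n_s * 10, 0, 1)
  expect_equal(nrow(detect_motion_segments(flat_accel, noisy_fnirs)), 0L)

  burst_accel <- flat_accel
  burst_accel[1, 15000:15500] <- burst_accel[1, 15000:15500] + 0.5
  flat_fnirs <- rnorm(n_s * 10, 0, 0.01)
  expect_equal(nrow(detect_motion_segments(burst_accel, flat_fnirs)), 0L)

  expect_error(detect_motion_segments(flat_accel[, 0], noisy_fnirs), "empty")
  expect_error(detect_motion_segments(flat_accel, noisy_fnirs,
                                      accel_thresh = -1), "positive")
})

test_that("an injected artifact is detected where accel and fNIRS co-spike", {
  cached <- cached_processed(32, "hard")
  tr <- cached$truth$artifacts
  expect_gt(nrow(tr), 0)
  det <- cached$proc$segments
  for (i in seq_len(nrow(tr))) {
    expect_true(any(det$start_s <= tr$start_s[i] + 1 &
                      det$end_s >= tr$end_s[i] - 1),
                info = sprintf("artifact %d covered", i))
  }
})

test_that("correct_motion reconstructs contaminated segments", {
  set.seed(21)
  t <- seq(0, 60, by = 0.1)
  clean <- sin(2 * pi * 0.05 * t) * 0.5
  seg <- data.frame(start_s = 20, end_s = 22)
  dirty <- clean
  dirty[t >= 20 & t < 22] <- dirty[t >= 20 & t < 22] + 10

  expect_identical(correct_motion(clean, seg[0, ]), clean)

  fixed <- correct_motion(dirty, seg, sample_rate = 10)
  idx <- t < 19.9 | t > 22.1
  expect_identical(fixed[idx], dirty[idx])
  rmse_before <- sqrt(mean((dirty - clean)^2))
  rmse_after <- sqrt(mean((fixed - clean)^2))
  expect_gt(rmse_before / rmse_after, 5)

  tail_seg <- data.frame(start_s = 59, end_s = 60.1)
  expect_no_error(correct_motion(dirty, tail_seg, sample_rate = 10))

  overlap <- data.frame(start_s = c(10, 11), end_s = c(12, 13))
  expect_error(correct_motion(clean, overlap, 10), "overlapping")
})

test_that("CBSI renders HbO and HbR perfectly anti-correlated", {
  set.seed(31)
  hbo <- rnorm(500)
  r1 <- cbsi(hbo, -hbo)
  expect_equal(r1$hbo, hbo)          # alpha = 1 identity

  hbr <- -0.4 * hbo + rnorm(500, 0, 0.3)
  r2 <- cbsi(hbo, hbr)
  expect_equal(cor(r2$hbo, r2$hbr), -1, tolerance = 1e-9)

  # hand arithmetic: sd equal so alpha = 1, hbo' = (hbo - hbr)/2
  r3 <- cbsi(c(1, 2, 3), c(3, 1, 2))
  expect_equal(r3$hbo, c(-1, 0.5, 0.5))
  expect_equal(r3$hbr, c(1, -0.5, -0.5))

  m <- rbind(rnorm(100), rep(1, 100))
  expect_error(cbsi(m, -m / 2), "channel 2")
})

test_that("heart rate is recovered from a synthetic ECG train", {
  hr60 <- rep(60, 600)
  ecg <- synthesize_ecg(hr60, 10, 250)
  est <- hr_from_ecg(ecg, 250, 10)
  expect_lt(abs(mean(est[50:550]) - 60), 1)

  # a missing beat produces an implausible 2.2-s RR that must be bridged
  set.seed(5)
  ecg2 <- rep(0, 250 * 30)
  beats <- seq(150, length(ecg2) - 150, by = 275)  # ~54.5 bpm
  beats <- beats[-13]
  for (b in beats) ecg2[b + (-5:5)] <- ecg2[b + (-5:5)] + exp(-0.5 * ((-5:5) / 2)^2)
  est2 <- hr_from_ecg(ecg2 + rnorm(length(ecg2), 0, 0.01), 250, 10)
  expect_false(anyNA(est2))
  expect_true(all(est2 > 45 & est2 < 65))

  expect_error(hr_from_ecg(rep(0, 250 * 20), 250), "R-peaks")
  expect_error(hr_from_ecg(rnorm(100), 250), "longer than 10 s")
})

test_that("stage order is enforced and recorded in provenance flags", {
  cached <- cached_processed(31, "hard")
  expect_equal(cached$proc$stages,
               c("mbll", "filtered", "motion_corrected", "cbsi"))
  rec <- cached$rec
  h_raw <- preprocess_session(rec, stages = "mbll")
  expect_error(hemo_cbsi(h_raw), "follow filtering")
  expect_error(hemo_motion_correct(h_raw, rec$accel), "follow filtering")
  expect_error(preprocess_session(rec, stages = c("mbll", "cbsi")),
               "in order")
  h_f <- hemo_filter(h_raw)
  expect_error(hemo_filter(h_f), "already filtered")
})

test_that("preprocessing recovers the simulated activation", {
  cors <- NULL
  for (p in c(31, 32)) {
    cached <- cached_processed(p, "hard")
    truth_f <- chebyshev_bandpass(cached$truth$hbo_clean)
    cors <- c(cors, vapply(1:8, function(ch)
      cor(cached$proc$hbo[ch, ], truth_f[ch, ]), numeric(1)))
  }
  expect_gte(mean(cors), 0.7)
})
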