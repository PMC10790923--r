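test_that("8-s windowing reproduces the 23-epoch count and partial policy", {
  w180 <- window_series(1800, 8, 10)
  expect_equal(nrow(w180), 23L)
  expect_equal(w180$start_s, seq(0, 176, by = 8))
  expect_equal(w180$end[23] - w180$start[23] + 1L, 40L)  # 4-s remainder kept

  expect_equal(nrow(window_series(80, 8, 10)), 1L)
  expect_equal(nrow(window_series(190, 8, 10)), 2L)  # 3-s remainder dropped
  expect_equal(nrow(window_series(200, 8, 10)), 3L)  # 4-s remainder kept
  expect_warning(w <- window_series(30, 8, 10), "zero windows")
  expect_equal(nrow(w), 0L)
  expect_error(window_series(0), "empty")
})

test_that("HbO window statistics match hand arithmetic", {
  const <- rep(3.5, 81)  # 8 s inclusive at 10 Hz
  expect_equal(hbo_stats(const), c(mean = 3.5, peak = 3.5, skew = 0,
                                   var = 0, auc = 8 * 3.5))
  w <- hbo_stats(0:9, sample_rate = 1)
  expect_equal(unname(w["mean"]), 4.5)
  expect_equal(unname(w["peak"]), 9)
  expect_equal(unname(w["var"]), 9.1667, tolerance = 1e-4)
  expect_equal(unname(w["skew"]), 0)
  expect_equal(unname(w["auc"]), 40.5)
  # a window with symmetric value distribution has zero skewness
  sym <- c(1, 2, 3, 4, 5)
  expect_equal(unname(hbo_stats(sym)["skew"]), 0)
  expect_error(hbo_stats(c(1, 2)), "3 samples")
})

test_that("heart-rate window statistics match hand arithmetic", {
  expect_equal(hr_stats(rep(60, 10)),
               c(avg = 60, median = 60, max = 60, min = 60, range = 0, sd = 0))
  s <- hr_stats(c(58, 60, 62, 64))
  expect_equal(unname(s[c("avg", "median", "max", "min", "range")]),
               c(61, 61, 64, 58, 6))
  expect_error(hr_stats(64), "2 samples")
})

test_that("Pearson connectivity is a correlation with the expected contracts", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_conn(x, 2 * x), 1)
  expect_equal(pearson_conn(x, -x + 3), -1)
  expect_equal(pearson_conn(x, c(1, 3, 2, 4)), 0.8)
  set.seed(8)
  for (i in 1:25) {
    a <- rnorm(40); b <- rnorm(40)
    r <- pearson_conn(a, b)
    expect_equal(r, pearson_oracle(a, b), tolerance = 1e-12)
    expect_gte(r, -1); expect_lte(r, 1)
    expect_identical(r, pearson_conn(b, a))
    expect_equal(pearson_conn(3 * a + 2, b), r, tolerance = 1e-12)
  }
  expect_warning(r0 <- pearson_conn(rep(1, 10), rnorm(10)), "zero-variance")
  expect_true(is.na(r0))
  expect_error(pearson_conn(1:3, 1:4), "equal length")
})

test_that("wavelet coherence behaves like a normalised cross-spectrum", {
  set.seed(14)
  x <- rnorm(900)
  expect_gte(wavelet_coherence(x, x), 0.99)
  lag <- c(x[-1], rnorm(1))
  expect_gte(wavelet_coherence(x, lag), 0.95)
  self_minus_noise <- replicate(10, {
    z <- rnorm(900)
    wavelet_coherence(z, z) - wavelet_coherence(z, rnorm(900))
  })
  expect_true(all(self_minus_noise >= 0))
  expect_error(wavelet_coherence(x, x, band = c(0.1, 6)), "Nyquist")
  expect_error(wavelet_coherence(x, rnorm(10)), "equal length")
})

test_that("independent white-noise pairs have low mean coherence", {
  set.seed(15)
  vals <- replicate(60, wavelet_coherence(rnorm(600), rnorm(600)))
  expect_lt(mean(vals), 0.5)
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("the feature table has the documented geometry", {
  expect_equal(length(feature_columns("fnirs")), 96L)  # 8*5 + 28*2
  expect_equal(length(feature_columns("hr")), 6L)
  expect_equal(ncol(utils::combn(8, 2)), 28L)
  expect_equal(choose(8, 2), 28L)

  proc <- cached_processed(32, "hard")$proc
  f <- assemble_features(list(proc))
  expect_s3_class(f, "epoch_features")
  expect_equal(nrow(f), 23L)  # game interval only: 180 s -> 23 epochs
  expect_true(all(feature_columns("fnirs") %in% names(f)))
  expect_true(all(feature_columns("hr") %in% names(f)))
  expect_equal(unique(f$demand), "Hard")
  expect_equal(unique(f$pain), "no_pain")
  expect_false(anyNA(f[, c(feature_columns("fnirs"), feature_columns("hr"))]))

  # purity: recomputing yields identical features
  f2 <- assemble_features(list(proc))
  expect_identical(f, f2)

  # truncation via max_duration_s follows the windowing policy
  f20 <- assemble_features(list(proc), max_duration_s = 20)
  expect_equal(nrow(f20), 3L)
})

test_that("assemble_features rejects unusable sessions", {
  proc <- cached_processed(32, "hard")$proc
  raw <- preprocess_session(cached_processed(32, "hard")$rec,
                            stages = c("mbll", "filtered"))
  expect_error(assemble_features(list(raw)), "CBSI")
  broken <- proc
  broken$hbo[3, ] <- NA_real_
  expect_error(assemble_features(list(broken)), "channel 3")
  no_game <- proc
  no_game$events <- data.frame(label = "rest", start_s = 0, end_s = 10)
  expect_error(assemble_features(list(no_game)), "no game event")
})
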