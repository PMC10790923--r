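test_that("canonical HRF peaks at the requested latency with unit amplitude", {
  h <- canonical_hrf(7, 10)
  expect_lte(abs(which.max(h) - 1 - 70), 1)
  expect_equal(max(h), 1)
  h14 <- canonical_hrf(14, 10)
  expect_lte(abs((which.max(h14) - 1) - 2 * (which.max(h) - 1)), 2)
  # convolution with a unit impulse reproduces the kernel
  x <- rep(0, 400); x[11] <- 1
  y <- gamenirs:::convolve_hrf(x, h)
  expect_equal(y[11:(10 + length(h))], h, tolerance = 1e-10)
  expect_error(canonical_hrf(0, 10), "peak_time")
  expect_error(canonical_hrf(7, -1), "sample_rate")
})

test_that("censored log-normal calibration hits its targets", {
  base <- calibrate_truncated_mean(22.5, 9.75, 180)
  expect_lt(base$p_censored, 0.01)
  expect_equal(exp(base$meanlog + base$sdlog^2 / 2), 22.5, tolerance = 0.5 / 22.5)
  # Monte-Carlo check of the numeric solve against an independent estimate
  hard <- calibrate_truncated_mean(74.07, 64.11, 180)
  set.seed(99)
  draws <- pmin(rlnorm(2e4, hard$meanlog, hard$sdlog), 180)
  expect_equal(mean(draws), 74.07, tolerance = 1.5 / 74.07)
  near_cap <- calibrate_truncated_mean(179.9, 30, 180)
  expect_gt(near_cap$p_censored, 0.4)
  expect_error(calibrate_truncated_mean(200, 30, 180), "infeasible")
  expect_error(calibrate_truncated_mean(50, -1, 180), "sd")
})

test_that("simulate_session is deterministic and honours its config", {
  cfg <- sim_config(n_participants = 2)
  a <- simulate_session(cfg, 1, "easy")
  b <- simulate_session(cfg, 1, "easy")
  expect_identical(a, b)
  expect_error(simulate_session(cfg, 1, "impossible"), "unknown condition")

  quiet <- sim_config(n_participants = 2,
                      artifact = list(rate_per_min = 0,
                                      step_amplitude_um = 5, burst_g = 0.5))
  s <- simulate_session(quiet, 1, "hard")
  expect_equal(nrow(s$truth$artifacts), 0L)

  null_cfg <- sim_config(n_participants = 2, demand_effect = 0)
  se <- simulate_session(null_cfg, 1, "easy")
  sh <- simulate_session(null_cfg, 1, "hard")
  expect_identical(se$truth$amplitude, sh$truth$amplitude)
})

test_that("game sessions carry a 180-s game and immersion starts with it", {
  cfg <- sim_config(n_participants = 2)
  s <- simulate_session(cfg, 2, "hard_pain")
  gi <- event_interval(s$recording, "game")
  expect_equal(gi[2] - gi[1], 180)
  im <- event_interval(s$recording, "immersion")
  expect_equal(im[1], gi[1])
  expect_lte(im[2] - im[1], 180)
  expect_equal(im[2] - im[1], min(s$truth$immersion_s, 180))
})

test_that("forward OD is exactly invertible in the artifact-free case", {
  cfg <- sim_config(n_participants = 2,
                    artifact = list(rate_per_min = 0, step_amplitude_um = 5,
                                    burst_g = 0.5))
  s <- simulate_session(cfg, 1, "hard")
  m <- default_montage()
  ext <- extinction_coefficients()
  for (ch in c(1, 5)) {
    conc <- mbll_inverse(s$recording$fnirs_od[ch, , ], m$separation[ch],
                         cfg$dpf, ext)
    expect_equal(conc$hbo, s$truth$hbo_full[ch, ], tolerance = 1e-10)
    expect_equal(conc$hbr, s$truth$hbr_full[ch, ], tolerance = 1e-10)
  }
})

test_that("heart rate is elevated during immersion by the configured effect", {
  cfg <- sim_config(n_participants = 8, pain_effect_hr = 20)
  found <- FALSE
  for (p in 1:8) {
    s <- simulate_session(cfg, p, "hard_pain")
    im <- event_interval(s$recording, "immersion")
    if (im[2] - im[1] < 40) next
    found <- TRUE
    hr <- s$recording$hr
    t <- (seq_along(hr) - 1) / 10
    during <- mean(hr[t >= im[1] + 10 & t < im[2] - 5])
    after <- mean(hr[t >= im[2] + 20])
    expect_gt(during - after, 10)
    break
  }
  expect_true(found)
})

test_that("simulate_cohort produces the full counterbalanced design", {
  cfg <- sim_config(n_participants = 4, seed = 3)
  co <- simulate_cohort(cfg)
  conds <- vapply(co$sessions, function(s) s$condition, character(1))
  expect_equal(sum(conds %in% c("easy", "hard", "easy_pain", "hard_pain")),
               4 * 4)
  expect_equal(sum(conds == "baseline"), 4)
  expect_equal(sum(conds == "cpt_only"), 4)
  # counterbalancing: participants do not share a first game condition
  expect_gt(length(unique(co$order[, 2])), 1)

  co2 <- simulate_cohort(sim_config(n_participants = 4, seed = 4))
  expect_equal(length(co2$sessions), length(co$sessions))
  art1 <- do.call(rbind, lapply(co$truth, `[[`, "artifacts"))
  art2 <- do.call(rbind, lapply(co2$truth, `[[`, "artifacts"))
  expect_false(identical(art1, art2))
})
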