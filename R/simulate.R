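# Synthetic cohort generator. Sessions are built forward through the same
# physics the preprocessing inverts: haemoglobin concentration courses are
# pushed through the modified Beer-Lambert law to optical density, motion
# steps are added in OD space time-locked to accelerometer bursts, and heart
# rate is synthesised directly as a smooth bpm series.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Calibrate a right-censored log-normal tolerance model
#'
#' Cold-pressor tolerance durations are modelled as log-normal and censored
#' at the protocol cap (immersion is stopped at \code{cap} seconds). Given a
#' target mean and standard deviation of the *observed* (censored) durations,
#' this solves numerically for the log-normal parameters whose censored
#' moments match, using the closed-form censored mean
#' \deqn{E[\min(X, c)] = e^{\mu+\sigma^2/2}\,\Phi\!\big(\tfrac{\ln c - \mu -
#'   \sigma^2}{\sigma}\big) + c\,\big(1 - \Phi(\tfrac{\ln c - \mu}{\sigma})\big)}
#' and the analogous second moment.
#'
#' @param target_mean Target censored mean, s (must lie in \code{(0, cap)}).
#' @param sd Target censored standard deviation, s (> 0).
#' @param cap Censoring point, s. Default 180.
#' @return List with \code{meanlog}, \code{sdlog}, \code{cap}, the achieved
#'   censored \code{mean} and \code{sd}, and the censoring probability
#'   \code{p_censored}.
#' @export
calibrate_truncated_mean <- function(target_mean, sd, cap = 180) {
  if (cap <= 0) stop("cap must be positive")
  if (target_mean <= 0) stop("target_mean must be positive")
  if (target_mean >= cap)
    stop("infeasible: target_mean (", target_mean,
         ") must be below the cap (", cap, ")")
  if (sd <= 0) stop("sd must be positive")
  cmean <- function(mu, sig)
    exp(mu + sig^2 / 2) * stats::pnorm((log(cap) - mu - sig^2) / sig) +
    cap * stats::pnorm((log(cap) - mu) / sig, lower.tail = FALSE)
  cm2 <- function(mu, sig)
    exp(2 * mu + 2 * sig^2) * stats::pnorm((log(cap) - mu - 2 * sig^2) / sig) +
    cap^2 * stats::pnorm((log(cap) - mu) / sig, lower.tail = FALSE)
  # profile solve: for any sigma, mu is pinned by the censored-mean equation
  # (cmean is increasing in mu with limit cap), then sigma is chosen to best
  # match the censored sd -- the mean target is always met exactly
  solve_mu <- function(sig)
    stats::uniroot(function(mu) cmean(mu, sig) - target_mean,
                   lower = log(target_mean) - 20,
                   upper = log(cap) + 20 * max(sig, 1), tol = 1e-12)$root
  sd_gap <- function(lsig) {
    sig <- exp(lsig)
    mu <- solve_mu(sig)
    m <- cmean(mu, sig)
    (sqrt(max(cm2(mu, sig) - m^2, 0)) - sd)^2
  }
  fit <- stats::optimize(sd_gap, lower = log(1e-3), upper = log(10),
                         tol = 1e-10)
  sig <- exp(fit$minimum)
  mu <- solve_mu(sig)
  m <- cmean(mu, sig)
  if (abs(m - target_mean) > 0.5)
    stop("calibration failed: censored mean ", signif(m, 4),
         " not within 0.5 s of target ", target_mean)
  list(meanlog = mu, sdlog = sig, cap = cap, mean = m,
       sd = sqrt(max(cm2(mu, sig) - m^2, 0)),
       p_censored = stats::pnorm((log(cap) - mu) / sig, lower.tail = FALSE))
}

#' Draw censored tolerance durations
#'
#' @param n Number of draws.
#' @param params A calibration from [calibrate_truncated_mean()].
#' @return Durations in seconds, capped at \code{params$cap}.
#' @export
rtolerance <- function(n, params) {
  pmin(stats::rlnorm(n, params$meanlog, params$sdlog), params$cap)
}

#' Simulation configuration
#'
#' Defaults define the cohort the package's tests and reports are built on:
#' 20 participants, 180-s games at 10 Hz, tolerance-duration models
#' calibrated to observed censored means/sds of 22.5 (9.75) s with no game,
#' 48.5 (35.73) s during Easy and 74.07 (64.11) s during Hard play, capped at
#' 180 s. Cortical activation is a sustained game boxcar plus discrete
#' gameplay events convolved with a 7-s-peak double-gamma HRF; physiological
#' nuisance is cardiac (1.1 Hz), respiratory (0.25 Hz) and Mayer-wave
#' (0.1 Hz) oscillation, white noise and slow drift, with amplitudes set so
#' the in-band (0.01-0.09 Hz) noise is comparable to the default demand
#' effect. HbR is anti-correlated with HbO (\code{hbr_ratio}) plus
#' independent noise.
#'
#' @param n_participants Cohort size. Default 20.
#' @param easy_amplitude HbO activation amplitude during Easy play, uM.
#' @param demand_effect Additional HbO amplitude during Hard play, uM.
#' @param pain_effect_hr Heart-rate elevation during immersion, bpm.
#' @param demand_effect_hr Heart-rate elevation during Hard play, bpm.
#' @param hrf_peak_time HRF time-to-peak, s.
#' @param noise List: oscillation frequencies (Hz) and amplitudes (uM),
#'   white-noise sd (uM), drift slope (uM/s).
#' @param artifact List: motion artifact \code{rate_per_min}, OD step
#'   amplitude expressed as an equivalent HbO step (\code{step_amplitude_um})
#'   and accelerometer burst amplitude (\code{burst_g}).
#' @param tolerance List of censored tolerance targets (means, sds, cap).
#' @param hbr_ratio HbR = -hbr_ratio * HbO + noise. Default 0.5.
#' @param hbr_noise_sd Independent HbR noise sd, uM.
#' @param event_rate_per_min Rate of discrete gameplay events feeding the
#'   HRF, per minute.
#' @param hr_baseline,hr_between_sd Population mean and between-participant
#'   sd of resting heart rate, bpm.
#' @param hr_noise_sd Within-session heart-rate variability, bpm.
#' @param dpf Differential pathlength factor used in the forward model.
#' @param game_s Game duration, s. Default 180.
#' @param with_ecg Also synthesise a 250-Hz ECG template train from the HR
#'   series. Default FALSE (the pipeline consumes HR statistics only).
#' @param seed Master seed; with the seed fixed the generator is
#'   bit-reproducible.
#' @return A list of class \code{"sim_config"} (tolerance models are
#'   pre-calibrated and cached in \code{$tolerance_models}).
#' @export
sim_config <- function(n_participants = 20,
                       easy_amplitude = 0.6,
                       demand_effect = 0.4,
                       pain_effect_hr = 8,
                       demand_effect_hr = 3,
                       hrf_peak_time = 7,
                       noise = list(cardiac_hz = 1.1, resp_hz = 0.25,
                                    mayer_hz = 0.1, cardiac_amp = 0.05,
                                    resp_amp = 0.08, mayer_amp = 0.12,
                                    white_sd = 0.1, drift_slope = 0.003),
                       artifact = list(rate_per_min = 1,
                                       step_amplitude_um = 5,
                                       burst_g = 0.5),
                       tolerance = list(baseline_mean_s = 22.5,
                                        baseline_sd_s = 9.75,
                                        easy_mean_s = 48.5,
                                        easy_sd_s = 35.73,
                                        hard_mean_s = 74.07,
                                        hard_sd_s = 64.11,
                                        cap_s = 180),
                       hbr_ratio = 0.5,
                       hbr_noise_sd = 0.03,
                       event_rate_per_min = 6,
                       hr_baseline = 70,
                       hr_between_sd = 5,
                       hr_noise_sd = 2,
                       dpf = 6,
                       game_s = 180,
                       with_ecg = FALSE,
                       seed = 1L) {
  if (tolerance$cap_s <= 0) stop("tolerance cap must be positive")
  sds <- c(tolerance$baseline_sd_s, tolerance$easy_sd_s, tolerance$hard_sd_s)
  if (any(sds <= 0)) stop("tolerance sds must be positive")
  if (hrf_peak_time <= 0) stop("hrf_peak_time must be positive")
  if (n_participants < 1) stop("n_participants must be at least 1")
  cfg <- list(n_participants = as.integer(n_participants),
              easy_amplitude = easy_amplitude,
              demand_effect = demand_effect,
              pain_effect_hr = pain_effect_hr,
              demand_effect_hr = demand_effect_hr,
              hrf_peak_time = hrf_peak_time,
              noise = noise, artifact = artifact, tolerance = tolerance,
              hbr_ratio = hbr_ratio, hbr_noise_sd = hbr_noise_sd,
              event_rate_per_min = event_rate_per_min,
              hr_baseline = hr_baseline, hr_between_sd = hr_between_sd,
              hr_noise_sd = hr_noise_sd, dpf = dpf, game_s = game_s,
              with_ecg = with_ecg, seed = as.integer(seed))
  cfg$tolerance_models <- list(
    baseline = calibrate_truncated_mean(tolerance$baseline_mean_s,
                                        tolerance$baseline_sd_s,
                                        tolerance$cap_s),
    easy = calibrate_truncated_mean(tolerance$easy_mean_s,
                                    tolerance$easy_sd_s, tolerance$cap_s),
    hard = calibrate_truncated_mean(tolerance$hard_mean_s,
                                    tolerance$hard_sd_s, tolerance$cap_s))
  class(cfg) <- "sim_config"
  cfg
}

# deterministic per-(participant, condition) seed stream, independent of
# cohort size so adding participants never perturbs existing sessions
session_seed <- function(config, participant, condition) {
  ci <- match(condition, SESSION_CONDITIONS)
  (as.numeric(config$seed) * 7919 + participant * 104729 + ci * 1299709) %%
    2147483629
}

smooth_box <- function(x, w) {
  if (w <= 1) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2)) |>
    (\(v) { v[is.na(v)] <- x[is.na(v)]; v })()
}

# place non-overlapping artifact intervals (>= 3 s apart)
draw_artifacts <- function(duration, rate_per_min) {
  n <- stats::rpois(1, rate_per_min * duration / 60)
  if (n == 0) return(data.frame(start_s = numeric(), end_s = numeric()))
  start <- sort(stats::runif(n, 2, duration - 4))
  dur <- stats::runif(n, 0.5, 2)
  keep <- rep(TRUE, n)
  last_end <- -Inf
  for (i in seq_len(n)) {
    if (start[i] < last_end + 3) keep[i] <- FALSE
    else last_end <- start[i] + dur[i]
  }
  data.frame(start_s = start[keep], end_s = start[keep] + dur[keep])
}

#' Simulate one participant-condition session
#'
#' Generates a [session_recording()] and its ground truth. Game sessions run
#' 10 s of rest, the game interval, then 10 s of rest; the immersion interval
#' of pain conditions starts with the game (the foot enters the water during
#' the countdown) and lasts a tolerance-model draw. Optical density is built
#' by the forward modified Beer-Lambert law from the simulated haemoglobin
#' courses, so preprocessing can invert it exactly; motion steps appear in OD
#' only inside accelerometer bursts.
#'
#' @param config A [sim_config()].
#' @param participant Participant index (1-based integer).
#' @param condition One of [SESSION_CONDITIONS].
#' @param seed Optional override of the derived per-session seed.
#' @return List with \code{recording} (a \code{session_recording}) and
#'   \code{truth} (activation amplitudes and clean course, artifact segments,
#'   immersion duration, HR profile).
#' @export
simulate_session <- function(config, participant, condition, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!condition %in% SESSION_CONDITIONS)
    stop("unknown condition: ", condition)
  if (is.null(seed)) seed <- session_seed(config, participant, condition)
  with_seed(seed, simulate_session_impl(config, participant, condition))
}

simulate_session_impl <- function(config, participant, condition) {
  fs <- FNIRS_RATE
  is_game <- condition %in% c("easy", "hard", "easy_pain", "hard_pain")
  demand <- if (grepl("hard", condition)) "hard" else "easy"
  pain <- condition %in% c("easy_pain", "hard_pain", "cpt_only")
  immersion <- NA_real_
  if (pain) {
    model <- if (condition == "cpt_only") config$tolerance_models$baseline
             else config$tolerance_models[[demand]]
    immersion <- rtolerance(1, model)
  }
  if (is_game) {
    pre <- 10; post <- 10
    duration <- pre + config$game_s + post
    events <- data.frame(label = "game", start_s = pre,
                         end_s = pre + config$game_s)
    if (pain) {
      imm_end <- min(pre + immersion, duration)
      events <- rbind(events, data.frame(label = "immersion", start_s = pre,
                                         end_s = imm_end))
    }
  } else if (condition == "baseline") {
    duration <- 90
    events <- data.frame(label = "rest", start_s = 0, end_s = 90)
  } else {  # cpt_only
    duration <- 10 + ceiling(immersion) + 10
    events <- data.frame(label = "immersion", start_s = 10,
                         end_s = 10 + immersion)
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs

  # --- cortical activation ---
  amplitude <- 0
  course <- rep(0, n)
  hrf <- canonical_hrf(config$hrf_peak_time, fs)
  if (is_game) {
    amplitude <- config$easy_amplitude +
      (demand == "hard") * config$demand_effect
    gi <- c(10, 10 + config$game_s)
    in_game <- t >= gi[1] & t < gi[2]
    # tonic game engagement plus phasic gameplay events, each normalised to
    # unit peak so `amplitude` is the peak response in uM; the phasic part
    # carries the power that survives the 0.01-0.09 Hz analysis band
    tonic <- convolve_hrf(as.numeric(in_game), hrf)
    tonic <- tonic / max(tonic)
    phasic <- rep(0, n)
    n_events <- stats::rpois(1, config$event_rate_per_min * config$game_s / 60)
    if (n_events > 0) {
      et <- stats::runif(n_events, gi[1], gi[2])
      idx <- pmin(round(et * fs) + 1, n)
      stim_e <- rep(0, n)
      stim_e[idx] <- stim_e[idx] + 1
      phasic <- convolve_hrf(stim_e, hrf)
      if (max(phasic) > 0) phasic <- phasic / max(phasic)
    }
    course <- 0.3 * tonic + 0.7 * phasic
  }
  gains <- stats::rnorm(8, 1, 0.2)
  gains[gains < 0.2] <- 0.2
  ns <- config$noise
  hbo <- matrix(0, 8, n)
  hbr <- matrix(0, 8, n)
  for (ch in 1:8) {
    osc <- ns$cardiac_amp * sin(2 * pi * ns$cardiac_hz * t +
                                  stats::runif(1, 0, 2 * pi)) +
      ns$resp_amp * sin(2 * pi * ns$resp_hz * t + stats::runif(1, 0, 2 * pi)) +
      ns$mayer_amp * sin(2 * pi * ns$mayer_hz * t + stats::runif(1, 0, 2 * pi))
    drift <- ns$drift_slope * sample(c(-1, 1), 1) * t
    hbo[ch, ] <- amplitude * gains[ch] * course + osc + drift +
      stats::rnorm(n, 0, ns$white_sd)
    hbr[ch, ] <- -config$hbr_ratio * hbo[ch, ] +
      stats::rnorm(n, 0, config$hbr_noise_sd)
  }

  # --- forward mBLL to optical density ---
  montage <- default_montage()
  ext <- extinction_coefficients(montage_wavelengths(montage))
  od <- array(0, dim = c(8, 2, n))
  for (ch in 1:8)
    od[ch, , ] <- mbll_forward(hbo[ch, ], hbr[ch, ],
                               montage$separation[ch], config$dpf, ext)

  # --- motion artifacts: OD steps inside accelerometer bursts ---
  art <- draw_artifacts(duration, config$artifact$rate_per_min)
  na <- round(duration * ACCEL_RATE)
  ta <- (seq_len(na) - 1) / ACCEL_RATE
  accel <- rbind(stats::rnorm(na, 0, 0.005),
                 stats::rnorm(na, 0, 0.005),
                 1 + stats::rnorm(na, 0, 0.005))
  if (nrow(art)) {
    step_od <- drop(ext[, "hbo"]) * config$artifact$step_amplitude_um *
      mean(montage$separation) * config$dpf
    for (i in seq_len(nrow(art))) {
      idx <- which(t >= art$start_s[i] & t < art$end_s[i])
      sgn <- sample(c(-1, 1), 1)
      for (w in 1:2)
        od[, w, idx] <- od[, w, idx] +
          sgn * step_od[w] * matrix(stats::runif(8, 0.5, 1.5), 8, length(idx))
      aidx <- which(ta >= art$start_s[i] & ta < art$end_s[i])
      axis <- sample(1:3, 1)
      burst <- config$artifact$burst_g *
        sin(2 * pi * 8 * ta[aidx]) *
        sin(pi * seq_along(aidx) / length(aidx))^2
      accel[axis, aidx] <- accel[axis, aidx] + burst
    }
  }

  # --- heart rate ---
  hr_rest <- config$hr_baseline + stats::rnorm(1, 0, config$hr_between_sd)
  hr <- rep(hr_rest, n)
  if (is_game) {
    in_game <- t >= 10 & t < 10 + config$game_s
    hr <- hr + (2 + (demand == "hard") * config$demand_effect_hr) *
      smooth_box(as.numeric(in_game), 5 * fs)
  }
  if (pain) {
    iv <- events[events$label == "immersion", ]
    in_imm <- t >= iv$start_s & t < iv$end_s
    hr <- hr + config$pain_effect_hr * smooth_box(as.numeric(in_imm), 5 * fs)
  }
  hr <- hr + 1.5 * sin(2 * pi * 0.25 * t + stats::runif(1, 0, 2 * pi)) +
    smooth_box(stats::rnorm(n, 0, config$hr_noise_sd * 3), 4 * fs)
  ecg <- if (config$with_ecg) synthesize_ecg(hr, fs, ECG_RATE) else NULL

  rec <- session_recording(sprintf("p%02d", participant), condition, od,
                           accel, ecg = ecg, hr = hr, events = events,
                           wavelengths = montage_wavelengths(montage))
  truth <- list(amplitude = amplitude, channel_gains = gains,
                activation = course * amplitude,
                hbo_clean = amplitude * outer(gains, course),
                hbo_full = hbo, hbr_full = hbr,
                artifacts = art, immersion_s = immersion,
                hr_rest = hr_rest)
  list(recording = rec, truth = truth)
}

montage_wavelengths <- function(montage) attr(montage, "wavelengths")

#' Synthesise an ECG template train from a heart-rate series
#'
#' Places Gaussian R-wave templates at the beat times implied by integrating
#' the instantaneous rate. A plumbing utility for exercising
#' [hr_from_ecg()]; not a physiologically detailed ECG model.
#'
#' @param hr Heart-rate series, bpm.
#' @param hr_rate Sampling rate of \code{hr}, Hz.
#' @param ecg_rate Output ECG sampling rate, Hz.
#' @return Numeric ECG vector.
#' @export
synthesize_ecg <- function(hr, hr_rate = 10, ecg_rate = 250) {
  duration <- length(hr) / hr_rate
  n <- round(duration * ecg_rate)
  t <- (seq_len(n) - 1) / ecg_rate
  inst <- stats::approx(seq_along(hr) / hr_rate, hr, t, rule = 2)$y
  phase <- cumsum(inst / 60) / ecg_rate
  beats <- which(diff(floor(phase)) > 0)
  ecg <- stats::rnorm(n, 0, 0.01)
  width <- round(0.02 * ecg_rate)
  kernel <- exp(-0.5 * ((-(2 * width):(2 * width)) / width)^2)
  for (b in beats) {
    idx <- b + (-(2 * width):(2 * width))
    ok <- idx >= 1 & idx <= n
    ecg[idx[ok]] <- ecg[idx[ok]] + kernel[ok]
  }
  ecg
}

#' Simulate a full cohort
#'
#' Each participant contributes the four game conditions (Easy/Hard crossed
#' with pain/no-pain) in a counterbalanced (Latin-square) order, one resting
#' baseline and one no-game cold-pressor session. Per-session seeds are
#' derived deterministically from the master seed and the participant index,
#' so cohorts are reproducible and individual sessions do not depend on
#' cohort size.
#'
#' @param config A [sim_config()].
#' @param conditions Conditions to generate per participant.
#' @return Object of class \code{"cohort"}: \code{sessions} (named list of
#'   \code{session_recording}), \code{truth} (parallel ground-truth list),
#'   \code{order} (condition presentation order per participant) and
#'   \code{config}.
#' @export
simulate_cohort <- function(config, conditions = SESSION_CONDITIONS) {
  stopifnot(inherits(config, "sim_config"))
  game_conds <- intersect(c("easy", "hard", "easy_pain", "hard_pain"),
                          conditions)
  extra <- intersect(c("baseline", "cpt_only"), conditions)
  latin <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 1), c(3, 4, 1, 2), c(4, 1, 2, 3))
  sessions <- list()
  truth <- list()
  order_tab <- NULL
  for (p in seq_len(config$n_participants)) {
    ord <- if (length(game_conds) == 4L)
      game_conds[latin[(p - 1L) %% 4L + 1L, ]] else game_conds
    for (cond in c(extra, ord)) {
      s <- simulate_session(config, p, cond)
      key <- sprintf("p%02d_%s", p, cond)
      sessions[[key]] <- s$recording
      truth[[key]] <- s$truth
    }
    if (length(ord))
      order_tab <- rbind(order_tab,
                         data.frame(participant = sprintf("p%02d", p),
                                    t(ord)))
  }
  structure(list(sessions = sessions, truth = truth, order = order_tab,
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  conds <- table(vapply(x$sessions, function(s) s$condition, character(1)))
  cat("Synthetic cohort:", x$config$n_participants, "participants,",
      length(x$sessions), "sessions\n")
  print(conds)
  invisible(x)
}
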