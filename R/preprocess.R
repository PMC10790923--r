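# Preprocessing: OD -> HbO/HbR via mBLL inversion, zero-phase band-pass,
# accelerometer-gated motion-segment detection and reconstruction, CBSI.
# Stage order is enforced through provenance flags on the series object.

#' Moving standard deviation
#'
#' Centred rolling standard deviation with edge windows truncated to the
#' available samples.
#'
#' @param x Numeric vector.
#' @param win Window length in samples (>= 2).
#' @return Vector of the same length as \code{x}.
#' @export
moving_sd <- function(x, win) {
  n <- length(x)
  if (n == 0) stop("empty series")
  win <- max(2L, as.integer(win))
  half <- win %/% 2L
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  m <- hi - lo + 1L
  s <- cs[hi + 1L] - cs[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  v <- (s2 - s^2 / m) / (m - 1L)
  sqrt(pmax(v, 0))
}

# gravity-removed accelerometer magnitude resampled to the fNIRS rate by
# windowed RMS over consecutive bins
accel_magnitude_10hz <- function(accel, accel_rate = ACCEL_RATE,
                                 target_rate = FNIRS_RATE) {
  if (!is.matrix(accel) || nrow(accel) != 3L)
    stop("accel must be a [3 x samples] matrix")
  mag <- sqrt(colSums((accel - rowMeans(accel))^2))
  bin <- accel_rate / target_rate
  n_out <- floor(ncol(accel) / bin)
  idx <- floor((seq_len(n_out * bin) - 1) / bin) + 1
  out <- sqrt(tapply(mag[seq_along(idx)]^2, idx, mean))
  as.numeric(out)
}

#' Detect motion-artifact segments from accelerometer and fNIRS agreement
#'
#' A segment is marked only where movement is visible in *both* streams: the
#' moving standard deviation (MSD) of the gravity-removed accelerometer
#' magnitude (resampled to the fNIRS rate by windowed RMS) exceeds its
#' threshold AND the MSD of the fNIRS series exceeds its own, within the same
#' resampled time window. Thresholds default to mean + 2 sd of each stream's
#' MSD over the session. Segments closer than 1 s are merged.
#'
#' @param accel \code{[3 x samples]} accelerometer matrix at
#'   \code{accel_rate}.
#' @param fnirs Numeric vector (single channel, or a summary across channels)
#'   at \code{sample_rate}.
#' @param sample_rate fNIRS sampling rate, Hz.
#' @param accel_rate Accelerometer sampling rate, Hz.
#' @param accel_msd_win,fnirs_msd_win MSD window lengths, s.
#' @param accel_thresh,fnirs_thresh Absolute MSD thresholds; \code{NULL}
#'   means mean + 2 sd of the stream's MSD.
#' @param merge_gap_s Segments separated by less than this many seconds are
#'   merged. Default 1.
#' @param dilate_s Half-width (s) by which each stream's exceedance mask is
#'   dilated before the conjunction, so the two streams need only spike
#'   within this distance of each other. Default 1.
#' @return \code{data.frame} with \code{start_s}, \code{end_s} (half-open,
#'   seconds) and \code{channel = "all"}.
#' @export
detect_motion_segments <- function(accel, fnirs, sample_rate = FNIRS_RATE,
                                   accel_rate = ACCEL_RATE,
                                   accel_msd_win = 1, fnirs_msd_win = 2,
                                   accel_thresh = NULL, fnirs_thresh = NULL,
                                   merge_gap_s = 1, dilate_s = 1) {
  if (length(fnirs) == 0 || ncol(accel) == 0) stop("empty streams")
  if (!is.null(accel_thresh) && accel_thresh <= 0)
    stop("thresholds must be positive")
  if (!is.null(fnirs_thresh) && fnirs_thresh <= 0)
    stop("thresholds must be positive")
  amag <- accel_magnitude_10hz(accel, accel_rate, sample_rate)
  n <- min(length(amag), length(fnirs))
  amsd <- moving_sd(amag[seq_len(n)], accel_msd_win * sample_rate)
  fmsd <- moving_sd(fnirs[seq_len(n)], fnirs_msd_win * sample_rate)
  if (is.null(accel_thresh)) accel_thresh <- mean(amsd) + 2 * stats::sd(amsd)
  if (is.null(fnirs_thresh)) fnirs_thresh <- mean(fmsd) + 2 * stats::sd(fmsd)
  # dilate each exceedance before the conjunction so the two streams only
  # need to spike within dilate_s of each other, not sample-aligned
  dilate <- function(v, half) {
    if (half < 1) return(v)
    idx <- which(v)
    out <- logical(length(v))
    for (i in idx)
      out[max(1, i - half):min(length(v), i + half)] <- TRUE
    out
  }
  half <- round(dilate_s * sample_rate)
  flag <- dilate(amsd > accel_thresh, half) &
    dilate(fmsd > fnirs_thresh, half)
  if (!any(flag))
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      channel = character()))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start_s = (starts[r$values] - 1L) / sample_rate,
                    end_s = ends[r$values] / sample_rate)
  # merge segments separated by less than merge_gap_s
  merged <- seg[1, ]
  for (i in seq_len(nrow(seg))[-1]) {
    if (seg$start_s[i] - merged$end_s[nrow(merged)] < merge_gap_s)
      merged$end_s[nrow(merged)] <- seg$end_s[i]
    else merged <- rbind(merged, seg[i, ])
  }
  merged$channel <- "all"
  merged
}

#' Reconstruct motion-contaminated segments
#'
#' Inside each segment, samples are replaced by linear interpolation between
#' the mean of a 2-s baseline before the segment and a 2-s baseline after it
#' (forward and backward baseline adjustment). A segment touching the start
#' or end of the series uses the single available baseline. Samples outside
#' segments are untouched.
#'
#' @param series Numeric vector.
#' @param segments \code{data.frame} with \code{start_s}, \code{end_s}
#'   (non-overlapping; overlapping segments are an error).
#' @param sample_rate Sampling rate, Hz.
#' @param baseline_s Baseline window length, s. Default 2.
#' @return Reconstructed series.
#' @export
correct_motion <- function(series, segments, sample_rate = FNIRS_RATE,
                           baseline_s = 2) {
  if (!nrow(segments)) return(series)
  seg <- segments[order(segments$start_s), ]
  if (any(seg$start_s[-1] < seg$end_s[-nrow(seg)]))
    stop("overlapping motion segments; merge before correcting")
  n <- length(series)
  if (any(seg$start_s < 0) || any(seg$end_s > n / sample_rate + 1e-9))
    stop("segments outside series extent")
  bl <- round(baseline_s * sample_rate)
  out <- series
  for (i in seq_len(nrow(seg))) {
    i1 <- max(1L, floor(seg$start_s[i] * sample_rate) + 1L)
    i2 <- min(n, ceiling(seg$end_s[i] * sample_rate))
    pre_idx <- max(1L, i1 - bl):(i1 - 1L)
    post_idx <- (i2 + 1L):min(n, i2 + bl)
    has_pre <- i1 > 1L
    has_post <- i2 < n
    pre_m <- if (has_pre) mean(series[pre_idx]) else NA_real_
    post_m <- if (has_post) mean(series[post_idx]) else NA_real_
    if (!has_pre && !has_post) stop("segment spans the entire series")
    if (!has_pre) pre_m <- post_m
    if (!has_post) post_m <- pre_m
    k <- i2 - i1 + 1L
    out[i1:i2] <- pre_m + (post_m - pre_m) * seq_len(k) / (k + 1L)
  }
  out
}

#' Correlation-based signal improvement (CBSI)
#'
#' Combines HbO and HbR under the physiological assumption that true
#' activation moves them in strict anti-phase while motion moves them in
#' phase. With \eqn{\alpha = sd(HbO)/sd(HbR)} per channel:
#' \deqn{HbO' = (HbO - \alpha\,HbR)/2, \qquad HbR' = -HbO'/\alpha,}
#' which renders the corrected pair perfectly negatively correlated.
#'
#' @param hbo,hbr Numeric vectors, or \code{[channels x samples]} matrices
#'   processed per channel.
#' @return List with corrected \code{hbo} and \code{hbr}.
#' @export
cbsi <- function(hbo, hbr) {
  if (is.matrix(hbo)) {
    stopifnot(is.matrix(hbr), all(dim(hbo) == dim(hbr)))
    out_o <- hbo; out_r <- hbr
    for (ch in seq_len(nrow(hbo))) {
      res <- cbsi_one(hbo[ch, ], hbr[ch, ], ch)
      out_o[ch, ] <- res$hbo; out_r[ch, ] <- res$hbr
    }
    return(list(hbo = out_o, hbr = out_r))
  }
  cbsi_one(hbo, hbr, 1L)
}

cbsi_one <- function(hbo, hbr, ch) {
  so <- stats::sd(hbo); sr <- stats::sd(hbr)
  if (so == 0 || sr == 0)
    stop("zero-variance channel ", ch, "; CBSI undefined")
  alpha <- so / sr
  h <- (hbo - alpha * hbr) / 2
  list(hbo = h, hbr = -h / alpha)
}

#' Heart rate from raw ECG
#'
#' Generic R-peak extraction: the ECG is band-passed (5-20 Hz), peaks are
#' detected by an adaptive threshold (60% of the 99th percentile of the
#' filtered amplitude) with a 0.3-s refractory period, physiologically
#' implausible RR intervals (< 0.3 s or > 2 s) are discarded, and the
#' beat-to-beat rate 60/RR is interpolated to a uniform series.
#'
#' @param ecg Numeric vector, raw ECG.
#' @param sample_rate ECG sampling rate, Hz. Default 250.
#' @param out_rate Output heart-rate sampling rate, Hz. Default 10.
#' @return Heart-rate series in bpm at \code{out_rate}.
#' @export
hr_from_ecg <- function(ecg, sample_rate = 250, out_rate = 10) {
  if (length(ecg) < 10 * sample_rate)
    stop("ecg must be longer than 10 s")
  bf <- signal::butter(2, c(5, 20) / (sample_rate / 2), type = "pass")
  f <- filtfilt_zi(bf$b, bf$a, ecg)
  q99 <- stats::quantile(abs(f), 0.99, names = FALSE)
  # a spiky signal has a heavy amplitude tail; gaussian noise or a flatline
  # does not, so refuse to threshold it
  if (q99 < 5 * stats::median(abs(f)) + .Machine$double.eps)
    stop("no detectable R-peaks in ECG")
  thr <- 0.6 * q99
  above <- f > thr
  refractory <- round(0.3 * sample_rate)
  peaks <- integer()
  i <- 1L
  n <- length(f)
  while (i <= n) {
    if (above[i]) {
      j <- min(i + refractory, n)
      peaks <- c(peaks, i - 1L + which.max(f[i:j]))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(peaks) < 3L) stop("no detectable R-peaks in ECG")
  rr <- diff(peaks) / sample_rate
  ok <- rr >= 0.3 & rr <= 2
  if (!any(ok)) stop("no physiologically plausible RR intervals")
  beat_t <- peaks[-1] / sample_rate
  t_out <- seq(0, length(ecg) / sample_rate, by = 1 / out_rate)
  stats::approx(beat_t[ok], 60 / rr[ok], t_out, rule = 2)$y
}

#' Preprocess a session into a hemodynamic series
#'
#' Runs the full fNIRS chain in its fixed order -- mBLL inversion, zero-phase
#' Chebyshev band-pass, accelerometer-gated motion correction, CBSI -- and
#' attaches provenance flags recording each completed stage. Heart rate is
#' taken from the recording's HR stream or derived from ECG via
#' [hr_from_ecg()].
#'
#' @param rec A [session_recording()].
#' @param montage A montage (defaults to the packaged one); supplies
#'   per-channel separations.
#' @param dpf Differential pathlength factor for the mBLL inversion.
#' @param stages Character vector of stages to run, in order; must be a
#'   prefix-closed subset of \code{c("mbll","filtered","motion_corrected",
#'   "cbsi")} in that order.
#' @param ... Passed to [detect_motion_segments()].
#' @return Object of class \code{"hemodynamic_series"}: \code{hbo},
#'   \code{hbr} (\code{[8 x samples]}, uM), \code{hr}, \code{sample_rate},
#'   \code{events}, \code{segments} (detected motion segments),
#'   \code{stages}, and the labels of the originating session.
#' @export
preprocess_session <- function(rec, montage = default_montage(), dpf = 6,
                               stages = c("mbll", "filtered",
                                          "motion_corrected", "cbsi"),
                               ...) {
  stopifnot(inherits(rec, "session_recording"))
  canonical <- c("mbll", "filtered", "motion_corrected", "cbsi")
  stages <- match.arg(stages, canonical, several.ok = TRUE)
  if (!identical(stages, canonical[seq_along(stages)]))
    stop("stages must be applied in order: ",
         paste(canonical, collapse = " -> "))
  ext <- extinction_coefficients(rec$wavelengths)
  n <- dim(rec$fnirs_od)[3]
  hbo <- matrix(0, 8, n)
  hbr <- matrix(0, 8, n)
  for (ch in 1:8) {
    conc <- mbll_inverse(rec$fnirs_od[ch, , ], montage$separation[ch],
                         dpf, ext)
    hbo[ch, ] <- conc$hbo
    hbr[ch, ] <- conc$hbr
  }
  h <- structure(list(hbo = hbo, hbr = hbr, sample_rate = FNIRS_RATE,
                      hr = rec$hr, events = rec$events,
                      participant_id = rec$participant_id,
                      condition = rec$condition,
                      segments = NULL, stages = "mbll"),
                 class = "hemodynamic_series")
  # detect motion on the unfiltered concentrations, where steps are still
  # sharp; the band-pass smears them over several seconds
  seg <- detect_motion_segments(rec$accel, colMeans(hbo), ...)
  if ("filtered" %in% stages) h <- hemo_filter(h)
  if ("motion_corrected" %in% stages)
    h <- hemo_motion_correct(h, rec$accel, segments = seg)
  if ("cbsi" %in% stages) h <- hemo_cbsi(h)
  if (is.null(h$hr) && !is.null(rec$ecg))
    h$hr <- hr_from_ecg(rec$ecg, rec$sample_rates$ecg, FNIRS_RATE)
  h
}

#' @rdname preprocess_session
#' @param h A \code{hemodynamic_series}.
#' @export
hemo_filter <- function(h, ...) {
  stopifnot(inherits(h, "hemodynamic_series"))
  if ("filtered" %in% h$stages) stop("series already filtered")
  h$hbo <- chebyshev_bandpass(h$hbo, sample_rate = h$sample_rate, ...)
  h$hbr <- chebyshev_bandpass(h$hbr, sample_rate = h$sample_rate, ...)
  h$stages <- c(h$stages, "filtered")
  h
}

#' @rdname preprocess_session
#' @param accel Accelerometer matrix for the same session.
#' @param segments Optional pre-computed motion segments; detected from
#'   \code{accel} and the channel-mean series when \code{NULL}.
#' @param pad_s Seconds by which each segment is widened before
#'   reconstruction, to cover artifact energy smeared by the preceding
#'   zero-phase band-pass. Default 3.
#' @export
hemo_motion_correct <- function(h, accel, segments = NULL, pad_s = 3, ...) {
  stopifnot(inherits(h, "hemodynamic_series"))
  if (!"filtered" %in% h$stages)
    stop("motion correction must follow filtering")
  seg <- if (is.null(segments))
    detect_motion_segments(accel, colMeans(h$hbo),
                           sample_rate = h$sample_rate, ...)
  else segments
  if (nrow(seg)) {
    dur <- ncol(h$hbo) / h$sample_rate
    seg$start_s <- pmax(seg$start_s - pad_s, 0)
    seg$end_s <- pmin(seg$end_s + pad_s, dur)
    seg <- merge_segments(seg)
    for (ch in seq_len(nrow(h$hbo))) {
      h$hbo[ch, ] <- correct_motion(h$hbo[ch, ], seg, h$sample_rate)
      h$hbr[ch, ] <- correct_motion(h$hbr[ch, ], seg, h$sample_rate)
    }
  }
  h$segments <- seg
  h$stages <- c(h$stages, "motion_corrected")
  h
}

merge_segments <- function(seg, gap = 0) {
  seg <- seg[order(seg$start_s), ]
  out <- seg[1, ]
  for (i in seq_len(nrow(seg))[-1]) {
    if (seg$start_s[i] - out$end_s[nrow(out)] <= gap)
      out$end_s[nrow(out)] <- max(out$end_s[nrow(out)], seg$end_s[i])
    else out <- rbind(out, seg[i, ])
  }
  out
}

#' @rdname preprocess_session
#' @export
hemo_cbsi <- function(h) {
  stopifnot(inherits(h, "hemodynamic_series"))
  if (!"filtered" %in% h$stages)
    stop("CBSI must follow filtering")
  res <- cbsi(h$hbo, h$hbr)
  h$hbo <- res$hbo
  h$hbr <- res$hbr
  h$stages <- c(h$stages, "cbsi")
  h
}

#' @export
print.hemodynamic_series <- function(x, ...) {
  cat("Hemodynamic series:", x$participant_id, "/", x$condition, "-",
      nrow(x$hbo), "channels x", ncol(x$hbo), "samples at",
      x$sample_rate, "Hz\n")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  if (!is.null(x$segments))
    cat("  motion segments:", nrow(x$segments), "\n")
  invisible(x)
}
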