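#' Canonical haemodynamic response function
#'
#' Double-gamma impulse response with the main peak repositioned to
#' \code{peak_time} seconds (the haemodynamic response takes roughly 7 s to
#' reach maximum amplitude) and an undershoot whose latency scales with the
#' peak and whose depth is 1/6 of the peak. The kernel is normalised to unit
#' peak amplitude and truncated to a finite support of \code{duration}
#' seconds.
#'
#' @param peak_time Time to peak, s (> 0). Default 7.
#' @param sample_rate Sampling rate, Hz (> 0).
#' @param duration Kernel support, s. Default 32.
#' @param undershoot_ratio Peak-to-undershoot amplitude ratio. Default 6.
#' @return Numeric kernel sampled at \code{sample_rate}, starting at t = 0.
#' @examples
#' h <- canonical_hrf(7, 10)
#' (which.max(h) - 1) / 10  # ~7 s
#' @export
canonical_hrf <- function(peak_time = 7, sample_rate = 10, duration = 32,
                          undershoot_ratio = 6) {
  if (peak_time <= 0) stop("peak_time must be positive")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (duration <= peak_time) stop("duration must exceed peak_time")
  t <- seq(0, duration, by = 1 / sample_rate)
  # gamma density with shape a and rate r peaks at (a-1)/r
  a1 <- 6; r1 <- (a1 - 1) / peak_time
  under_peak <- peak_time * 16 / 6   # keeps the canonical 6 s / 16 s ratio
  a2 <- 16; r2 <- (a2 - 1) / under_peak
  h <- stats::dgamma(t, shape = a1, rate = r1) -
    stats::dgamma(t, shape = a2, rate = r2) / undershoot_ratio
  h / max(h)
}

# convolve a stimulus course with the HRF, keeping the input length
convolve_hrf <- function(x, hrf) {
  y <- stats::convolve(c(x, rep(0, length(hrf))), rev(hrf), type = "open")
  y[seq_along(x)]
}
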