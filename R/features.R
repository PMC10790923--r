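# Windowed feature extraction: per-channel HbO statistics, heart-rate
# statistics, and two channel-pair connectivity measures (Pearson
# correlation within the window; Morlet wavelet coherence computed on the
# full series and averaged within the window).

#' Split a series into consecutive 8-s windows
#'
#' Non-overlapping windows of \code{window_s} seconds; a final partial window
#' is retained when it covers at least \code{min_partial_s} seconds (so a
#' 180-s game at 10 Hz yields 22 full windows plus one 4-s remainder = 23
#' epochs).
#'
#' @param n_samples Number of samples in the series.
#' @param window_s Window length, s. Default 8.
#' @param sample_rate Sampling rate, Hz.
#' @param min_partial_s Minimum length of a retained partial window, s.
#' @return \code{data.frame} with columns \code{start} and \code{end} (sample
#'   indices, inclusive) and \code{start_s}; zero rows (with a warning) when
#'   the series is shorter than \code{min_partial_s}.
#' @export
window_series <- function(n_samples, window_s = 8, sample_rate = FNIRS_RATE,
                          min_partial_s = 4) {
  if (n_samples < 1) stop("series is empty")
  wlen <- round(window_s * sample_rate)
  min_len <- round(min_partial_s * sample_rate)
  if (n_samples < min_len) {
    warning("series shorter than ", min_partial_s, " s; zero windows")
    return(data.frame(start = integer(), end = integer(),
                      start_s = numeric()))
  }
  starts <- seq(1L, n_samples, by = wlen)
  ends <- pmin(starts + wlen - 1L, n_samples)
  keep <- (ends - starts + 1L) >= min_len
  data.frame(start = starts[keep], end = ends[keep],
             start_s = (starts[keep] - 1L) / sample_rate)
}

#' Descriptive statistics of an HbO window
#'
#' Mean, peak (maximum value), adjusted Fisher-Pearson sample skewness
#' (defined as 0 for a zero-variance window), unbiased sample variance, and
#' area under the curve as the trapezoidal integral of the signed signal over
#' time (uM s).
#'
#' @param window Numeric vector (>= 3 samples).
#' @param sample_rate Sampling rate, Hz.
#' @return Named vector \code{(mean, peak, skew, var, auc)}.
#' @export
hbo_stats <- function(window, sample_rate = FNIRS_RATE) {
  n <- length(window)
  if (n < 3) stop("hbo_stats needs at least 3 samples")
  m <- mean(window)
  v <- stats::var(window)
  if (v == 0) sk <- 0
  else {
    m2 <- mean((window - m)^2)
    m3 <- mean((window - m)^3)
    g1 <- m3 / m2^1.5
    sk <- g1 * sqrt(n * (n - 1)) / (n - 2)
  }
  dt <- 1 / sample_rate
  auc <- sum((window[-1] + window[-n]) / 2) * dt
  c(mean = m, peak = max(window), skew = sk, var = v, auc = auc)
}

#' Descriptive statistics of a heart-rate window
#'
#' @param window Numeric vector, bpm (>= 2 samples).
#' @return Named vector \code{(avg, median, max, min, range, sd)}.
#' @export
hr_stats <- function(window) {
  if (length(window) < 2) stop("hr_stats needs at least 2 samples")
  c(avg = mean(window), median = stats::median(window), max = max(window),
    min = min(window), range = max(window) - min(window),
    sd = stats::sd(window))
}

#' Pearson correlation between two channel windows
#'
#' Covariance normalised by the two standard deviations. Zero-variance input
#' leaves the coefficient undefined; it is returned as \code{NA} with a
#' warning rather than an error so that a flat window degrades a single
#' feature, not the whole epoch.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in \code{[-1, 1]}, or \code{NA}.
#' @export
pearson_conn <- function(x, y) {
  if (length(x) != length(y)) stop("windows must have equal length")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    warning("zero-variance window; Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cov(x, y) / (sx * sy)
}

# ---------------------------------------------------------------------------
# Morlet continuous wavelet transform and magnitude-squared wavelet coherence
# ---------------------------------------------------------------------------

# scales (s, seconds) covering [f_min, f_max] with n_voices per octave;
# Fourier frequency of an omega0 = 6 Morlet is ~0.9680 / s
morlet_scales <- function(f_min, f_max, n_voices = 12, omega0 = 6) {
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  s_min <- 1 / (fourier_factor * f_max)
  s_max <- 1 / (fourier_factor * f_min)
  n <- ceiling(log2(s_max / s_min) * n_voices)
  s <- s_min * 2^(seq(0, n) / n_voices)
  list(scales = s, freqs = 1 / (fourier_factor * s),
       fourier_factor = fourier_factor)
}

# CWT by FFT (batched over scales): rows = scales, cols = time
morlet_cwt <- function(x, dt, scales, omega0 = 6) {
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  xh <- stats::fft(c(x - mean(x), rep(0, npad - n)))
  omega <- 2 * pi * c(0:(npad / 2), -((npad / 2 - 1):1)) / (npad * dt)
  pos <- omega > 0
  # columns = scales: daughter-wavelet spectra times the signal spectrum
  Psi <- vapply(scales, function(s)
    pi^(-0.25) * sqrt(2 * pi * s / dt) *
      exp(-0.5 * (s * omega - omega0)^2) * pos, numeric(npad))
  W <- stats::mvfft(Psi * xh, inverse = TRUE)[seq_len(n), , drop = FALSE] /
    npad
  t(W)
}

# smoothing operator: Gaussian in time with sd matched to each scale
# (applied in the frequency domain, zero-padded against wrap-around), boxcar
# across 0.6 octave in scale (without smoothing, coherence is identically 1)
smooth_timescale <- function(M, scales, dt, n_voices = 12,
                             scale_window_oct = 0.6, kernels = NULL) {
  n <- ncol(M)
  n_s <- length(scales)
  if (is.null(kernels))
    kernels <- smoothing_kernels(n, scales, dt, n_voices, scale_window_oct)
  Mp <- rbind(t(M), matrix(0, kernels$npad - n, n_s))
  sm <- stats::mvfft(stats::mvfft(Mp) * kernels$G, inverse = TRUE) /
    kernels$npad
  out <- t(sm[seq_len(n), , drop = FALSE])
  if (!is.null(kernels$B)) out <- kernels$B %*% out
  out
}

# precomputed smoothing operators: frequency response of the scale-matched
# Gaussian (per scale) and the row-normalised 0.6-octave boxcar across scales
smoothing_kernels <- function(n, scales, dt, n_voices = 12,
                              scale_window_oct = 0.6) {
  # pad far enough that the circular Gaussian tail cannot wrap around
  npad <- stats::nextn(n + ceiling(4 * max(scales) / dt), c(2, 3, 5))
  omega <- 2 * pi * c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1)) / npad
  G <- vapply(scales / dt, function(s_samp) exp(-0.5 * (s_samp * omega)^2),
              numeric(npad))
  n_s <- length(scales)
  win <- max(1L, round(scale_window_oct * n_voices))
  B <- NULL
  if (win > 1L && n_s > 1L) {
    lo <- pmax(seq_len(n_s) - win %/% 2L, 1L)
    hi <- pmin(seq_len(n_s) + win %/% 2L, n_s)
    B <- matrix(0, n_s, n_s)
    for (k in seq_len(n_s)) B[k, lo[k]:hi[k]] <- 1 / (hi[k] - lo[k] + 1L)
  }
  list(npad = npad, G = G, B = B)
}

#' Magnitude-squared wavelet coherence between two series
#'
#' Analytic Morlet (omega0 = 6) continuous wavelet transform with 12 voices
#' per octave; the cross- and auto-spectra are scale-normalised and smoothed
#' in time (Gaussian matched to each scale) and across scale (0.6-octave
#' boxcar) before forming
#' \deqn{R^2(s, t) = \frac{|S(W_{xy}/s)|^2}{S(|W_x|^2/s)\, S(|W_y|^2/s)}.}
#' Values inside the cone of influence (edge distance shorter than the
#' e-folding time \eqn{\sqrt{2}s}) are masked. The scalar summary is the mean
#' over the requested frequency band and, optionally, over a set of time
#' windows (see \code{windows}); band-limited coherence at 0.08 Hz needs more
#' than 8 s of context, which is why coherence is computed on the full series
#' and then averaged within each window.
#'
#' @param x,y Numeric vectors of equal length.
#' @param band Frequency band, Hz, \code{c(low, high)}. Default
#'   \code{c(0.08, 0.3125)}.
#' @param sample_rate Sampling rate, Hz.
#' @param windows Optional window table from [window_series()]; when given,
#'   the return value is the per-window band-mean vector.
#' @return Mean coherence in \code{[0, 1]} (or a vector per window).
#' @export
wavelet_coherence <- function(x, y, band = c(0.08, 0.3125),
                              sample_rate = FNIRS_RATE, windows = NULL) {
  if (length(x) != length(y)) stop("series must have equal length")
  nyq <- sample_rate / 2
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    stop("band must be increasing and lie within (0, Nyquist)")
  R2 <- wcoh_map(list(x, y), sample_rate, band)$R2[[1]]
  band_window_mean(R2, windows)
}

# coherence maps for all unordered pairs of a list of series; returns masked
# band-restricted maps to share the per-channel CWTs across pairs
wcoh_map <- function(series_list, sample_rate, band = c(0.08, 0.3125),
                     n_voices = 12, omega0 = 6) {
  dt <- 1 / sample_rate
  n <- length(series_list[[1]])
  # half an octave of margin so scale smoothing at the band edges is fair
  sc <- morlet_scales(band[1] / 2^0.5, min(band[2] * 2^0.5, 0.95 / dt / 2),
                      n_voices, omega0)
  W <- lapply(series_list, morlet_cwt, dt = dt, scales = sc$scales,
              omega0 = omega0)
  kern <- smoothing_kernels(n, sc$scales, dt, n_voices)
  Ssm <- lapply(W, function(w)
    Re(smooth_timescale(w * Conj(w) / sc$scales, sc$scales, dt, n_voices,
                        kernels = kern)))
  in_band <- sc$freqs >= band[1] & sc$freqs <= band[2]
  # cone of influence: e-folding time sqrt(2) * s from either edge
  tt <- (seq_len(n) - 1) * dt
  edge <- pmin(tt, rev(tt))
  coi_ok <- outer(sc$scales * sqrt(2), edge, `<=`)
  pairs <- utils::combn(length(series_list), 2)
  R2 <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    Sxy <- smooth_timescale(W[[i]] * Conj(W[[j]]) / sc$scales, sc$scales,
                            dt, n_voices, kernels = kern)
    r2 <- Mod(Sxy)^2 / (Ssm[[i]] * Ssm[[j]])
    r2 <- pmin(pmax(r2, 0), 1)
    raw <- r2
    raw[!in_band, ] <- NA
    r2[!coi_ok] <- NA
    r2[!in_band, ] <- NA
    attr(r2, "raw") <- raw
    R2[[p]] <- r2
  }
  list(R2 = R2, pairs = pairs, freqs = sc$freqs)
}

# band mean outside the cone of influence; a window lying entirely inside
# the cone (e.g. a short partial window at the series edge) falls back to
# the unmasked band mean rather than going missing
band_window_mean <- function(R2, windows) {
  raw <- attr(R2, "raw")
  one <- function(cols) {
    m <- mean(R2[, cols], na.rm = TRUE)
    if (is.nan(m) && !is.null(raw)) m <- mean(raw[, cols], na.rm = TRUE)
    m
  }
  if (is.null(windows)) return(one(seq_len(ncol(R2))))
  vapply(seq_len(nrow(windows)), function(w)
    one(windows$start[w]:windows$end[w]), numeric(1))
}

# ---------------------------------------------------------------------------
# feature-table assembly
# ---------------------------------------------------------------------------

hbo_stat_names <- function()
  as.vector(t(outer(1:8, c("mean", "peak", "skew", "var", "auc"),
                    function(ch, s) sprintf("ch%d_%s", ch, s))))

conn_names <- function() {
  pairs <- utils::combn(8, 2)
  as.vector(rbind(sprintf("conn_ch%d_ch%d_pearson", pairs[1, ], pairs[2, ]),
                  sprintf("conn_ch%d_ch%d_wcoh", pairs[1, ], pairs[2, ])))
}

hr_stat_names <- function()
  sprintf("hr_%s", c("avg", "median", "max", "min", "range", "sd"))

session_labels <- function(condition) {
  if (condition %in% c("baseline", "cpt_only"))
    stop("no demand label for condition ", condition)
  list(demand = if (grepl("hard", condition)) "Hard" else "Easy",
       pain = if (grepl("pain", condition)) "pain" else "no_pain")
}

#' Assemble the epoch feature table for a set of processed game sessions
#'
#' Crops each session to its game interval, windows it into 8-s epochs, and
#' computes per-epoch features: 8 channels x 5 HbO statistics (40), 28
#' channel pairs x \{Pearson, wavelet coherence\} (56), and 6 heart-rate
#' statistics, with participant, demand and pain labels. Wavelet coherence is
#' computed once per pair on the full game-length series and averaged within
#' each window.
#'
#' @param sessions List of \code{hemodynamic_series} from
#'   [preprocess_session()] (game conditions only, fully preprocessed).
#' @param max_duration_s Optional per-session cap on the analysed game time,
#'   seconds from game start (used by duration matching).
#' @return \code{data.frame} of class \code{"epoch_features"}: 96 fNIRS + 6
#'   HR feature columns plus \code{participant_id}, \code{demand},
#'   \code{pain}, \code{window}, \code{window_start_s}.
#' @export
assemble_features <- function(sessions, max_duration_s = NULL) {
  rows <- lapply(sessions, function(h) {
    stopifnot(inherits(h, "hemodynamic_series"))
    if (!"cbsi" %in% h$stages)
      stop("sessions must be fully preprocessed (CBSI stage missing for ",
           h$participant_id, "/", h$condition, ")")
    labs <- session_labels(h$condition)
    gi <- event_interval(h, "game")
    if (is.null(gi)) stop("session ", h$participant_id, "/", h$condition,
                          " has no game event")
    if (!is.null(max_duration_s))
      gi[2] <- min(gi[2], gi[1] + max_duration_s)
    fs <- h$sample_rate
    idx <- (floor(gi[1] * fs) + 1L):min(ncol(h$hbo), ceiling(gi[2] * fs))
    hbo <- h$hbo[, idx, drop = FALSE]
    if (any(apply(hbo, 1, function(r) all(!is.finite(r))))) {
      bad <- which(apply(hbo, 1, function(r) all(!is.finite(r))))[1]
      stop("channel ", bad, " is all-missing in ", h$participant_id, "/",
           h$condition)
    }
    hr <- if (!is.null(h$hr)) h$hr[pmin(idx, length(h$hr))]
          else stop("no heart-rate series for ", h$participant_id, "/",
                    h$condition)
    win <- window_series(ncol(hbo), sample_rate = fs)
    if (!nrow(win)) return(NULL)
    stats40 <- t(apply(win, 1, function(w) {
      as.vector(t(apply(hbo[, w[1]:w[2], drop = FALSE], 1, hbo_stats,
                        sample_rate = fs)))
    }))
    hr6 <- t(apply(win, 1, function(w) hr_stats(hr[w[1]:w[2]])))
    wc <- wcoh_map(lapply(seq_len(nrow(hbo)), function(ch) hbo[ch, ]), fs)
    conn <- matrix(NA_real_, nrow(win), 56)
    for (p in seq_len(ncol(wc$pairs))) {
      i <- wc$pairs[1, p]; j <- wc$pairs[2, p]
      pe <- vapply(seq_len(nrow(win)), function(w)
        pearson_conn(hbo[i, win$start[w]:win$end[w]],
                     hbo[j, win$start[w]:win$end[w]]), numeric(1))
      conn[, 2 * p - 1] <- pe
      conn[, 2 * p] <- band_window_mean(wc$R2[[p]], win)
    }
    out <- data.frame(stats40, conn, hr6)
    names(out) <- c(hbo_stat_names(), conn_names(), hr_stat_names())
    out$participant_id <- h$participant_id
    out$demand <- labs$demand
    out$pain <- labs$pain
    out$window <- seq_len(nrow(win))
    out$window_start_s <- win$start_s
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {  # e.g. every matched duration shorter than one window
    tab <- as.data.frame(matrix(numeric(), 0, 102,
                                dimnames = list(NULL,
                                                c(hbo_stat_names(),
                                                  conn_names(),
                                                  hr_stat_names()))))
    tab$participant_id <- character()
    tab$demand <- character()
    tab$pain <- character()
    tab$window <- integer()
    tab$window_start_s <- numeric()
    class(tab) <- c("epoch_features", "data.frame")
    return(tab)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (anyNA(tab$demand) || anyNA(tab$pain)) stop("missing labels")
  class(tab) <- c("epoch_features", "data.frame")
  tab
}

#' Names of the feature column groups
#'
#' @param stream \code{"fnirs"} (40 statistics + 56 connectivity = 96
#'   columns) or \code{"hr"} (6 columns).
#' @return Character vector of column names.
#' @export
feature_columns <- function(stream = c("fnirs", "hr")) {
  stream <- match.arg(stream)
  if (stream == "fnirs") c(hbo_stat_names(), conn_names()) else hr_stat_names()
}
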