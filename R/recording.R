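#' Conditions recognised by the pipeline
#'
#' Four game conditions (two demand levels crossed with cold-pressor pain),
#' plus the resting baseline and the no-game cold-pressor test.
#' @export
SESSION_CONDITIONS <- c("easy", "hard", "easy_pain", "hard_pain",
                        "baseline", "cpt_only")

FNIRS_RATE <- 10    # Hz
ACCEL_RATE <- 512   # Hz
ECG_RATE   <- 250   # Hz

#' Construct a session recording
#'
#' Bundles the synchronised raw streams of one participant-condition: fNIRS
#' optical density (8 channels x 2 wavelengths at 10 Hz), 3-axis
#' accelerometer (512 Hz), and either raw ECG (250 Hz) or a precomputed
#' heart-rate series (10 Hz), together with event annotations. All streams
#' share a common time origin (t = 0 at recording start); event intervals are
#' half-open \code{[start, end)} in seconds.
#'
#' @param participant_id Character scalar.
#' @param condition One of [SESSION_CONDITIONS].
#' @param fnirs_od Numeric array \code{[channels x wavelengths x samples]}.
#' @param accel Numeric matrix \code{[3 x samples]} in g.
#' @param ecg Optional numeric vector (mV-scale, arbitrary units).
#' @param hr Optional numeric vector, beats per minute at 10 Hz.
#' @param events \code{data.frame} with columns \code{label},
#'   \code{start_s}, \code{end_s}. A \code{"game"} event, when present, must
#'   not exceed 185 s.
#' @param wavelengths Pair of nm values matching the second array dimension.
#' @return An object of class \code{"session_recording"}.
#' @export
session_recording <- function(participant_id, condition, fnirs_od, accel,
                              ecg = NULL, hr = NULL,
                              events = data.frame(label = character(),
                                                  start_s = numeric(),
                                                  end_s = numeric()),
                              wavelengths = c(761, 847)) {
  condition <- match.arg(condition, SESSION_CONDITIONS)
  if (length(dim(fnirs_od)) != 3L)
    stop("fnirs_od must be a [channels x wavelengths x samples] array")
  if (dim(fnirs_od)[2] != 2L)
    stop("fnirs_od must carry exactly 2 wavelengths")
  if (!is.matrix(accel) || nrow(accel) != 3L)
    stop("accel must be a [3 x samples] matrix")
  if (is.null(ecg) && is.null(hr))
    stop("at least one of ecg / hr must be present")
  duration <- dim(fnirs_od)[3] / FNIRS_RATE
  stopifnot(is.data.frame(events),
            all(c("label", "start_s", "end_s") %in% names(events)))
  if (nrow(events)) {
    if (any(events$end_s <= events$start_s))
      stop("event intervals must satisfy end_s > start_s")
    if (any(events$start_s < 0 | events$end_s > duration + 1 / FNIRS_RATE))
      stop("event intervals must lie within the recording (0, ",
           round(duration, 1), " s)")
    game <- events[events$label == "game", ]
    if (nrow(game) && any(game$end_s - game$start_s > 185))
      stop("game interval exceeds 185 s")
  }
  structure(list(participant_id = as.character(participant_id),
                 condition = condition,
                 fnirs_od = fnirs_od,
                 accel = accel,
                 ecg = ecg,
                 hr = hr,
                 events = events,
                 wavelengths = sort(as.numeric(wavelengths)),
                 sample_rates = list(fnirs = FNIRS_RATE, accel = ACCEL_RATE,
                                     ecg = ECG_RATE, hr = FNIRS_RATE)),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat("Session recording:", x$participant_id, "/", x$condition, "\n")
  cat("  fNIRS OD:", dim(x$fnirs_od)[1], "channels x",
      dim(x$fnirs_od)[2], "wavelengths,",
      round(dim(x$fnirs_od)[3] / x$sample_rates$fnirs, 1), "s at",
      x$sample_rates$fnirs, "Hz\n")
  cat("  accel:", ncol(x$accel), "samples at", x$sample_rates$accel, "Hz;",
      if (is.null(x$ecg)) "no ECG;" else "ECG present;",
      if (is.null(x$hr)) "no HR series\n" else "HR series present\n")
  if (nrow(x$events)) {
    cat("  events:\n")
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("    %-10s [%6.1f, %6.1f) s\n", x$events$label[i],
                  x$events$start_s[i], x$events$end_s[i]))
  }
  invisible(x)
}

#' Interval of a named event
#'
#' @param rec A \code{session_recording} (or anything with an \code{events}
#'   data.frame).
#' @param label Event label, e.g. \code{"game"} or \code{"immersion"}.
#' @return \code{c(start_s, end_s)} or \code{NULL} when absent.
#' @export
event_interval <- function(rec, label) {
  ev <- rec$events[rec$events$label == label, ]
  if (!nrow(ev)) return(NULL)
  c(ev$start_s[1], ev$end_s[1])
}

# exact-precision CSV writer: %.17g guarantees a bit-exact double round trip
write_exact_csv <- function(df, path) {
  fmt1 <- function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }
  cols <- lapply(df, fmt1)
  lines <- do.call(paste, c(cols, sep = ","))
  writeLines(c(paste(names(df), collapse = ","), lines), path)
}

#' Write a session recording to a directory of CSV files
#'
#' The package's documented CSV dialect: one header line, comma-separated,
#' first column \code{time} in seconds from the stream origin, numeric values
#' printed with 17 significant digits so that a write/read cycle is bit-exact
#' for doubles. Streams are written as \code{fnirs.csv} (columns
#' \code{ch<i>_wl<nm>}), \code{accel.csv} (\code{x,y,z}), optional
#' \code{ecg.csv} and \code{hr.csv}, and a \code{meta.json} sidecar carrying
#' participant, condition, wavelengths, sample rates and the event table.
#'
#' @param rec A \code{session_recording}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "session_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(rec$fnirs_od)[3]
  od <- matrix(aperm(rec$fnirs_od, c(3, 1, 2)), nrow = n)
  nm <- as.vector(outer(seq_len(dim(rec$fnirs_od)[1]), rec$wavelengths,
                        function(ch, wl) sprintf("ch%d_wl%d", ch, wl)))
  df <- data.frame((seq_len(n) - 1) / rec$sample_rates$fnirs, od)
  names(df) <- c("time", nm)
  write_exact_csv(df, file.path(dir, "fnirs.csv"))
  na <- ncol(rec$accel)
  adf <- data.frame(time = (seq_len(na) - 1) / rec$sample_rates$accel,
                    x = rec$accel[1, ], y = rec$accel[2, ], z = rec$accel[3, ])
  write_exact_csv(adf, file.path(dir, "accel.csv"))
  if (!is.null(rec$ecg))
    write_exact_csv(data.frame(
      time = (seq_along(rec$ecg) - 1) / rec$sample_rates$ecg,
      ecg = rec$ecg), file.path(dir, "ecg.csv"))
  if (!is.null(rec$hr))
    write_exact_csv(data.frame(
      time = (seq_along(rec$hr) - 1) / rec$sample_rates$hr,
      bpm = rec$hr), file.path(dir, "hr.csv"))
  meta <- list(participant_id = rec$participant_id,
               condition = rec$condition,
               wavelengths = rec$wavelengths,
               sample_rates = rec$sample_rates,
               events = rec$events)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

check_rate <- function(time, declared, stream) {
  if (length(time) < 2L) return(invisible())
  implied <- 1 / stats::median(diff(time))
  if (abs(implied - declared) > 0.02 * declared)
    stop("sampling-rate mismatch in ", stream, ": header declares ",
         declared, " Hz but timestamps imply ", signif(implied, 4), " Hz")
}

#' Read a session recording written by [write_recording()]
#'
#' Validates that every required stream is present and that timestamp spacing
#' agrees with the declared sampling rate (within 2%).
#'
#' @param dir Directory containing the CSV streams and \code{meta.json}.
#' @return A \code{session_recording}.
#' @export
read_recording <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("missing stream: meta.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  need <- c("fnirs.csv", "accel.csv")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("missing stream: ", f, " in ", dir)
  fn <- utils::read.csv(file.path(dir, "fnirs.csv"), check.names = FALSE)
  check_rate(fn$time, meta$sample_rates$fnirs, "fnirs.csv")
  wl <- sort(as.numeric(meta$wavelengths))
  n_ch <- (ncol(fn) - 1L) / 2L
  od <- array(NA_real_, dim = c(n_ch, 2L, nrow(fn)))
  for (ch in seq_len(n_ch))
    for (w in 1:2) {
      col <- sprintf("ch%d_wl%d", ch, wl[w])
      if (!col %in% names(fn)) stop("fnirs.csv is missing column ", col)
      od[ch, w, ] <- fn[[col]]
    }
  ac <- utils::read.csv(file.path(dir, "accel.csv"))
  check_rate(ac$time, meta$sample_rates$accel, "accel.csv")
  ecg <- hr <- NULL
  if (file.exists(file.path(dir, "ecg.csv"))) {
    ec <- utils::read.csv(file.path(dir, "ecg.csv"))
    check_rate(ec$time, meta$sample_rates$ecg, "ecg.csv")
    ecg <- ec$ecg
  }
  if (file.exists(file.path(dir, "hr.csv"))) {
    hc <- utils::read.csv(file.path(dir, "hr.csv"))
    check_rate(hc$time, meta$sample_rates$hr, "hr.csv")
    hr <- hc$bpm
  }
  events <- as.data.frame(meta$events)
  if (!nrow(events))
    events <- data.frame(label = character(), start_s = numeric(),
                         end_s = numeric())
  session_recording(meta$participant_id, meta$condition, od,
                    rbind(ac$x, ac$y, ac$z), ecg = ecg, hr = hr,
                    events = events, wavelengths = wl)
}

#' Write the fNIRS stream of a recording as a SNIRF (HDF5) file
#'
#' Minimal SNIRF layout: \code{/formatVersion}, \code{/nirs/data1} with
#' \code{dataTimeSeries} (samples x measurements), \code{time}, and one
#' \code{measurementList<k>} group per column carrying source, detector and
#' wavelength indices; probe wavelengths under \code{/nirs/probe}. Requires
#' the \pkg{rhdf5} package. Events and the non-optical streams stay in the
#' CSV dialect (see [write_recording()]); SNIRF round trips are exact to
#' float tolerance only.
#'
#' @param rec A \code{session_recording}.
#' @param path Output \code{.snirf} file path (overwritten).
#' @return \code{path}, invisibly.
#' @export
write_snirf <- function(rec, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("SNIRF support requires the rhdf5 package")
  stopifnot(inherits(rec, "session_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write("1.0", path, "formatVersion")
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/data1")
  n <- dim(rec$fnirs_od)[3]
  n_ch <- dim(rec$fnirs_od)[1]
  dts <- matrix(aperm(rec$fnirs_od, c(3, 1, 2)), nrow = n)
  rhdf5::h5write(dts, path, "nirs/data1/dataTimeSeries")
  rhdf5::h5write((seq_len(n) - 1) / rec$sample_rates$fnirs, path,
                 "nirs/data1/time")
  k <- 0L
  for (w in 1:2)
    for (ch in seq_len(n_ch)) {
      k <- k + 1L
      grp <- sprintf("nirs/data1/measurementList%d", k)
      rhdf5::h5createGroup(path, grp)
      rhdf5::h5write(ch, path, paste0(grp, "/sourceIndex"))
      rhdf5::h5write(ch, path, paste0(grp, "/detectorIndex"))
      rhdf5::h5write(w, path, paste0(grp, "/wavelengthIndex"))
      rhdf5::h5write(1L, path, paste0(grp, "/dataType"))
    }
  rhdf5::h5createGroup(path, "nirs/probe")
  rhdf5::h5write(rec$wavelengths, path, "nirs/probe/wavelengths")
  rhdf5::H5close()
  invisible(path)
}

#' Read the fNIRS optical-density array from a SNIRF file
#'
#' @param path A \code{.snirf} file written by [write_snirf()] (or any file
#'   following the same minimal layout).
#' @return List with \code{fnirs_od} (\code{[channels x wavelengths x
#'   samples]}), \code{time} and \code{wavelengths}.
#' @export
read_snirf <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("SNIRF support requires the rhdf5 package")
  if (!file.exists(path)) stop("SNIRF file not found: ", path)
  contents <- rhdf5::h5ls(path)
  dts <- rhdf5::h5read(path, "nirs/data1/dataTimeSeries")
  time <- as.numeric(rhdf5::h5read(path, "nirs/data1/time"))
  wl <- as.numeric(rhdf5::h5read(path, "nirs/probe/wavelengths"))
  ml <- grep("^measurementList", contents$name[contents$group == "/nirs/data1"],
             value = TRUE)
  n_meas <- ncol(dts)
  if (length(unique(ml)) < n_meas)
    stop("SNIRF file has ", n_meas, " measurement columns but only ",
         length(unique(ml)), " measurementList entries")
  src <- wli <- integer(n_meas)
  for (k in seq_len(n_meas)) {
    grp <- sprintf("nirs/data1/measurementList%d", k)
    items <- contents$name[contents$group == paste0("/", grp)]
    if (!"wavelengthIndex" %in% items)
      stop("SNIRF measurementList", k, " is missing wavelengthIndex")
    src[k] <- as.integer(rhdf5::h5read(path, paste0(grp, "/sourceIndex")))
    wli[k] <- as.integer(rhdf5::h5read(path, paste0(grp, "/wavelengthIndex")))
  }
  rhdf5::H5close()
  n_ch <- max(src)
  od <- array(NA_real_, dim = c(n_ch, 2L, nrow(dts)))
  for (k in seq_len(n_meas)) od[src[k], wli[k], ] <- dts[, k]
  list(fnirs_od = od, time = time, wavelengths = wl)
}
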