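#' Euclidean source-detector distance in centimetres
#'
#' Computes the straight-line distance between a source and a detector optode
#' from their MNI coordinates. Coordinates are given in millimetres (the unit
#' in which MNI coordinates are conventionally tabulated); the returned
#' separation is in centimetres, the unit used for fNIRS channel geometry.
#'
#' @param source_mni Numeric 3-vector, source optode MNI coordinates (mm).
#' @param detector_mni Numeric 3-vector, detector optode MNI coordinates (mm).
#' @return Separation in cm (not rounded; use [format_distance()] for the
#'   conventional 2-decimal display).
#' @examples
#' optode_distance(c(0.312, 58.512, 66.462), c(0.231, 80.771, 35.417))
#' @export
optode_distance <- function(source_mni, detector_mni) {
  source_mni <- as.numeric(source_mni)
  detector_mni <- as.numeric(detector_mni)
  if (length(source_mni) != 3L || length(detector_mni) != 3L)
    stop("optode coordinates must be 3-vectors (x, y, z in mm)")
  if (!all(is.finite(source_mni)) || !all(is.finite(detector_mni)))
    stop("optode coordinates must be finite")
  sqrt(sum((source_mni - detector_mni)^2)) / 10
}

#' Display a separation to two decimals
#'
#' Rounding is half-even (base \code{round()}), matching how channel
#' separations are conventionally printed.
#'
#' @param d Separation(s) in cm.
#' @return Numeric, rounded to 2 decimals.
#' @export
format_distance <- function(d) round(d, 2)

#' Read a montage table
#'
#' Reads a tab-separated montage definition with one row per channel and
#' columns \code{channel_id}, \code{source_label}, \code{detector_label},
#' \code{source_x/y/z}, \code{detector_x/y/z} (MNI, mm) and optionally a
#' stored \code{separation_cm}. Separations are always recomputed from the
#' coordinates; when a stored value disagrees with the recomputed one by more
#' than \code{tol} cm a warning identifies the channel (the recomputed value
#' is kept).
#'
#' The montage contract for this pipeline is fixed: exactly 8 channels fed by
#' exactly 2 distinct sources, recorded at two wavelengths.
#'
#' @param path Path to the TSV file.
#' @param wavelengths Pair of wavelengths in nm emitted by the sources.
#' @param tol Cross-check tolerance (cm) between stored and recomputed
#'   separations.
#' @return A \code{data.frame} of class \code{"montage"} with the recomputed
#'   \code{separation} column (cm) and, when present in the file, the stored
#'   value as \code{separation_stored}.
#' @seealso [default_montage()] for the montage shipped with the package.
#' @export
load_montage <- function(path, wavelengths = c(761, 847), tol = 0.005) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("channel_id", "source_label", "detector_label",
                "source_x", "source_y", "source_z",
                "detector_x", "detector_y", "detector_z")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("montage table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  coord_cols <- required[4:9]
  for (cc in coord_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[cc]]))))
    if (length(bad))
      stop("non-numeric coordinate in montage row ", bad[1],
           " (column ", cc, ")")
    tab[[cc]] <- as.numeric(tab[[cc]])
  }
  if (anyDuplicated(tab$channel_id))
    stop("duplicate channel_id in montage: ",
         paste(unique(tab$channel_id[duplicated(tab$channel_id)]),
               collapse = ", "))
  if (nrow(tab) != 8L)
    stop("montage must define exactly 8 channels, found ", nrow(tab))
  if (length(unique(tab$source_label)) != 2L)
    stop("montage must use exactly 2 distinct sources, found ",
         length(unique(tab$source_label)))
  sep <- vapply(seq_len(nrow(tab)), function(i) {
    optode_distance(unlist(tab[i, c("source_x", "source_y", "source_z")]),
                    unlist(tab[i, c("detector_x", "detector_y", "detector_z")]))
  }, numeric(1))
  if (any(sep <= 0)) stop("zero source-detector separation in montage")
  if ("separation_cm" %in% names(tab)) {
    stored <- as.numeric(tab$separation_cm)
    off <- which(abs(stored - sep) > tol)
    if (length(off))
      warning("stored separation differs from coordinates for channel(s) ",
              paste(tab$channel_id[off], collapse = ", "),
              " (stored ", paste(stored[off], collapse = ", "),
              " vs recomputed ",
              paste(format_distance(sep[off]), collapse = ", "), " cm)")
    tab$separation_stored <- stored
    tab$separation_cm <- NULL
  }
  tab$separation <- sep
  if (length(wavelengths) != 2L) stop("exactly two wavelengths expected")
  attr(tab, "wavelengths") <- sort(as.numeric(wavelengths))
  class(tab) <- c("montage", "data.frame")
  tab
}

#' The midline frontal/central-parietal montage shipped with the package
#'
#' Eight channels between two midline sources (Fz feeding detectors AFZ, F2,
#' FCz, F1; CPz feeding Cz, CP2, Pz, CP1), with separations between about
#' 2.85 and 3.90 cm, recorded at 761 and 847 nm. The file also stores the
#' separations as originally tabulated; one of them (channel 2) disagrees
#' with its own coordinates by 0.02 cm, which \code{load_montage} reports as
#' a warning.
#'
#' @return A \code{"montage"} data.frame (see [load_montage()]).
#' @export
default_montage <- function() {
  if (is.null(.gamenirs$montage)) {
    path <- system.file("extdata", "midline_montage.tsv", package = "gamenirs")
    .gamenirs$montage <- suppressWarnings(load_montage(path))
  }
  .gamenirs$montage
}

.gamenirs <- new.env(parent = emptyenv())
.gamenirs$montage <- NULL

#' @export
print.montage <- function(x, ...) {
  cat("fNIRS montage:", nrow(x), "channels,",
      length(unique(x$source_label)), "sources, wavelengths",
      paste(attr(x, "wavelengths"), collapse = "/"), "nm\n")
  df <- data.frame(channel = x$channel_id,
                   source = x$source_label,
                   detector = x$detector_label,
                   separation_cm = format_distance(x$separation))
  print(df, row.names = FALSE)
  invisible(x)
}
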