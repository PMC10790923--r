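#' Molar extinction coefficients for oxy/deoxy-haemoglobin
#'
#' Values interpolated from the standard compiled haemoglobin absorption
#' tables (Gratzer/Cope compilation, as distributed with common fNIRS
#' toolboxes), converted to cm^-1 per micromolar. Rows are wavelengths, the
#' columns are HbO and HbR. At 761 nm deoxy-haemoglobin dominates; above the
#' ~800 nm isosbestic point the order reverses, which is what makes the
#' two-wavelength inversion well conditioned.
#'
#' @param wavelengths Numeric vector of wavelengths (nm); only 761 and 847
#'   are tabulated here.
#' @return Matrix \code{[wavelength x chromophore]} in cm^-1 uM^-1.
#' @export
extinction_coefficients <- function(wavelengths = c(761, 847)) {
  tab <- rbind("761" = c(hbo = 1465.1, hbr = 3712.4),
               "847" = c(hbo = 2504.7, hbr = 1818.7))
  key <- as.character(round(wavelengths))
  if (!all(key %in% rownames(tab)))
    stop("extinction coefficients tabulated only for 761 and 847 nm")
  tab[key, , drop = FALSE] * 1e-6  # cm^-1 M^-1 -> cm^-1 uM^-1
}

check_extinction <- function(extinction) {
  if (!is.matrix(extinction) || any(dim(extinction) != c(2L, 2L)))
    stop("extinction must be a 2 x 2 matrix (2 wavelengths x {HbO, HbR})")
  if (abs(det(extinction)) < .Machine$double.eps * max(abs(extinction))^2 ||
      det(extinction) == 0)
    stop("extinction matrix is singular; wavelengths do not separate HbO/HbR")
  invisible(extinction)
}

#' Forward modified Beer-Lambert law
#'
#' Maps concentration changes to optical-density changes:
#' \deqn{\Delta OD_\lambda = (\epsilon_{HbO,\lambda}\,\Delta HbO +
#'   \epsilon_{HbR,\lambda}\,\Delta HbR)\; L \; DPF}
#' with \eqn{L} the source-detector separation (cm) and DPF the differential
#' pathlength factor. This is the generative model the synthetic-session
#' simulator uses, and the exact inverse of [mbll_inverse()].
#'
#' @param hbo,hbr Numeric vectors, concentration change in uM.
#' @param separation Source-detector separation, cm.
#' @param dpf Differential pathlength factor (default 6, configurable).
#' @param extinction 2 x 2 matrix as from [extinction_coefficients()].
#' @return Matrix \code{[2 wavelengths x samples]} of OD changes.
#' @export
mbll_forward <- function(hbo, hbr, separation, dpf = 6,
                         extinction = extinction_coefficients()) {
  check_extinction(extinction)
  if (separation <= 0) stop("separation must be positive")
  extinction %*% rbind(hbo, hbr) * (separation * dpf)
}

#' Invert the modified Beer-Lambert law
#'
#' Solves the per-sample 2-wavelength linear system for \code{(HbO, HbR)}
#' concentration changes from optical-density changes.
#'
#' @param od Matrix \code{[2 wavelengths x samples]} of OD changes (a length-2
#'   vector is treated as one sample).
#' @param separation Source-detector separation, cm.
#' @param dpf Differential pathlength factor.
#' @param extinction 2 x 2 matrix, wavelengths x {HbO, HbR}.
#' @return List with numeric vectors \code{hbo} and \code{hbr} (uM).
#' @export
mbll_inverse <- function(od, separation, dpf = 6,
                         extinction = extinction_coefficients()) {
  if (is.vector(od)) od <- matrix(od, ncol = 1)
  if (nrow(od) != 2L)
    stop("od must carry exactly 2 wavelengths (rows), found ", nrow(od))
  check_extinction(extinction)
  if (separation <= 0) stop("separation must be positive")
  conc <- solve(extinction, od) / (separation * dpf)
  list(hbo = unname(conc[1, ]), hbr = unname(conc[2, ]))
}
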