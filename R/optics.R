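#' Optics configuration for the modified Beer-Lambert law
#'
#' Describes the dual-wavelength measurement: specific extinction
#' coefficients of deoxy- and oxyhemoglobin at the two wavelengths, the
#' differential path-length factors (DPF), and the source-detector
#' separation. Defaults use standard tabulated extinction coefficients for
#' 695 nm and 830 nm in 1/(mM*cm), a DPF of 6 at both wavelengths, and a
#' 3 cm separation (continuous-wave fNIRS convention). Because the same
#' configuration drives both the forward model and the inversion, all
#' downstream statistics (correlations) are invariant to the particular
#' table chosen.
#'
#' @param wavelengths numeric length-2, wavelengths in nm.
#' @param ext_hb,ext_hbo2 numeric length-2, extinction coefficients of Hb
#'   and HbO2 at the two wavelengths, 1/(mM*cm).
#' @param dpf numeric length-2, differential path-length factor per
#'   wavelength (dimensionless).
#' @param distance source-detector distance in cm.
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(wavelengths = c(695, 830),
                          ext_hb = c(1.85, 0.693),
                          ext_hbo2 = c(0.30, 0.974),
                          dpf = c(6, 6),
                          distance = 3) {
  stopifnot(length(wavelengths) == 2L, length(ext_hb) == 2L,
            length(ext_hbo2) == 2L, length(dpf) == 2L)
  if (distance <= 0) stopf("source-detector distance must be > 0 cm")
  # per-wavelength rows of the 2x2 system OD = E %*% c(hb, hbo2)
  E <- cbind(hb = ext_hb, hbo2 = ext_hbo2) * dpf * distance
  if (abs(det(E)) < .Machine$double.eps * max(abs(E))^2)
    stopf("extinction matrix is singular; chromophores are not separable")
  if (kappa(E, exact = TRUE) > 1e8)
    stopf("extinction matrix is ill-conditioned (condition number > 1e8)")
  structure(list(wavelengths = wavelengths, ext_hb = ext_hb,
                 ext_hbo2 = ext_hbo2, dpf = dpf, distance = distance,
                 E = E),
            class = "optics_config")
}

#' Optical-density series container
#'
#' @param data numeric array samples x channels x 2 wavelengths of optical
#'   density changes (dimensionless).
#' @param fs sampling rate in Hz.
#' @param channel_ids character channel identifiers.
#' @param wavelengths numeric length-2 wavelengths in nm.
#' @return An object of class `od_series`.
#' @export
od_series <- function(data, fs, channel_ids = NULL,
                      wavelengths = c(695, 830)) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3L] == 2L)
  if (fs <= 0) stopf("sampling rate must be positive")
  if (!all(is.finite(data))) stopf("optical density data contain non-finite values")
  channel_ids <- channel_ids %||% sprintf("ch%02d", seq_len(dim(data)[2L]))
  structure(list(data = data, fs = fs, channel_ids = channel_ids,
                 wavelengths = wavelengths),
            class = "od_series")
}

#' Hemoglobin concentration-change series container
#'
#' Holds per-channel oxy- (`hbo2`) and deoxyhemoglobin (`hb`)
#' concentration-change time series plus provenance flags recording which
#' preprocessing stages have been applied.
#'
#' @param hbo2,hb numeric matrices samples x channels.
#' @param fs sampling rate in Hz.
#' @param channel_ids character channel identifiers.
#' @param stages character vector of applied stage names.
#' @return An object of class `hemo_series`.
#' @export
hemo_series <- function(hbo2, hb, fs, channel_ids = NULL,
                        stages = character()) {
  hbo2 <- as.matrix(hbo2); hb <- as.matrix(hb)
  stopifnot(identical(dim(hbo2), dim(hb)))
  if (fs <= 0) stopf("sampling rate must be positive")
  channel_ids <- channel_ids %||% sprintf("ch%02d", seq_len(ncol(hbo2)))
  stopifnot(length(channel_ids) == ncol(hbo2))
  structure(list(hbo2 = hbo2, hb = hb, fs = fs,
                 channel_ids = channel_ids, stages = stages),
            class = "hemo_series")
}

#' @export
print.hemo_series <- function(x, ...) {
  cat(sprintf("<hemo_series> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$hbo2), ncol(x$hbo2), x$fs, nrow(x$hbo2) / x$fs))
  cat("  stages:", if (length(x$stages)) paste(x$stages, collapse = " -> ")
      else "(raw)", "\n")
  invisible(x)
}

#' Forward modified Beer-Lambert model
#'
#' Maps hemoglobin concentration changes to dual-wavelength optical-density
#' changes: `dOD_l = (a_Hb,l * dHb + a_HbO2,l * dHbO2) * DPF_l * d` per
#' channel and sample. Used by the synthetic generator; the exact inverse is
#' [beer_lambert_invert()].
#'
#' @param hemo a [hemo_series()].
#' @param optics an [optics_config()].
#' @return An [od_series()].
#' @export
forward_optics <- function(hemo, optics = optics_config()) {
  stopifnot(inherits(hemo, "hemo_series"), inherits(optics, "optics_config"))
  E <- optics$E
  n <- nrow(hemo$hbo2); p <- ncol(hemo$hbo2)
  od <- array(0, dim = c(n, p, 2L))
  for (w in 1:2)
    od[, , w] <- E[w, "hb"] * hemo$hb + E[w, "hbo2"] * hemo$hbo2
  od_series(od, fs = hemo$fs, channel_ids = hemo$channel_ids,
            wavelengths = optics$wavelengths)
}

#' Invert the modified Beer-Lambert law
#'
#' Solves, per sample and channel, the two-wavelength linear system for
#' (dHb, dHbO2). Exact inverse of [forward_optics()] under the same
#' configuration.
#'
#' @param od an [od_series()].
#' @param optics an [optics_config()]; must be non-singular (checked at
#'   construction).
#' @return A [hemo_series()] with stage flag `"beer_lambert"`.
#' @export
beer_lambert_invert <- function(od, optics = optics_config()) {
  stopifnot(inherits(od, "od_series"), inherits(optics, "optics_config"))
  Einv <- solve(optics$E)
  od1 <- od$data[, , 1L, drop = TRUE]
  od2 <- od$data[, , 2L, drop = TRUE]
  # keep matrix shape for single-channel input
  if (is.null(dim(od1))) { od1 <- matrix(od1); od2 <- matrix(od2) }
  hb   <- Einv[1L, 1L] * od1 + Einv[1L, 2L] * od2
  hbo2 <- Einv[2L, 1L] * od1 + Einv[2L, 2L] * od2
  hemo_series(hbo2, hb, fs = od$fs, channel_ids = od$channel_ids,
              stages = "beer_lambert")
}
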