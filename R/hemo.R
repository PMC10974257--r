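#' Optical configuration for hemoglobin conversion
#'
#' Defaults describe a dual-wavelength (735/850 nm) continuous-wave system.
#' The shipped extinction coefficients are approximate literature values in
#' 1/(mM cm) and, like the differential pathlength factor, are calibration-
#' dependent: replace them with instrument-specific values for quantitative
#' work.
#'
#' @param wavelengths Wavelength pair in nm.
#' @param extinction 2 x 2 matrix of molar extinction coefficients,
#'   rows = wavelengths, columns = `c("HbO", "HbR")`, in 1/(mM cm).
#' @param separation Source-detector distance in cm.
#' @param dpf Differential pathlength factor per wavelength.
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(wavelengths = c(735, 850),
                           extinction = matrix(c(0.45, 1.10,
                                                 1.06, 0.78),
                                               nrow = 2, byrow = TRUE,
                                               dimnames = list(c("735", "850"),
                                                               c("HbO", "HbR"))),
                           separation = 3, dpf = c(6, 6)) {
  if (separation <= 0) stop_config("separation must be > 0")
  if (any(dpf <= 0)) stop_config("dpf must be > 0")
  if (abs(det(extinction)) < 1e-12)
    stop_config("extinction matrix is singular")
  structure(list(wavelengths = wavelengths, extinction = extinction,
                 separation = separation, dpf = dpf),
            class = "optical_config")
}

#' De-interleave a time-division-multiplexed intensity stream
#'
#' Continuous-wave systems alternate the active source per ADC frame; this
#' splits the interleaved stream into one intensity trace per source at the
#' per-source rate.  A trailing partial frame is dropped with a warning.
#'
#' @param stream Interleaved samples.
#' @param frame Number of interleaved sources per frame.
#' @param labels Optional names for the output traces.
#' @return Named list of `frame` traces.
#' @export
demultiplex <- function(stream, frame = 2, labels = NULL) {
  n <- length(stream)
  nf <- n %/% frame
  if (n %% frame != 0) {
    warning("partial trailing frame dropped")
    stream <- stream[seq_len(nf * frame)]
  }
  m <- matrix(stream, nrow = frame)
  out <- lapply(seq_len(frame), function(i) m[i, ])
  names(out) <- if (!is.null(labels)) labels else paste0("source", seq_len(frame))
  out
}

#' Optical-density change relative to a baseline window
#'
#' `dOD(t) = log10(I0 / I(t))` with `I0` the mean intensity over the baseline
#' window.
#'
#' @param intensity Positive intensity trace.
#' @param baseline_window Indices defining the baseline; defaults to the whole
#'   trace.
#' @return dOD trace of the same length.
#' @export
od_change <- function(intensity, baseline_window = seq_along(intensity)) {
  if (any(intensity <= 0)) stop_data("intensities must be positive")
  i0 <- mean(intensity[baseline_window])
  log10(i0 / intensity)
}

#' Modified Beer-Lambert inversion to hemoglobin concentration changes
#'
#' Solves, per sample, the 2 x 2 system
#' `dOD_lambda = (eps_HbO * dHbO + eps_HbR * dHbR) * d * DPF_lambda`
#' for the oxy- and deoxy-hemoglobin concentration changes.
#'
#' @param dod_1,dod_2 Equal-length dOD traces at the two wavelengths, ordered
#'   as the rows of the extinction matrix.
#' @param config An [optical_config()].
#' @return List with `HbO` and `HbR` concentration-change traces in uM.
#' @export
mbll <- function(dod_1, dod_2, config = optical_config()) {
  if (length(dod_1) != length(dod_2)) stop_data("dOD traces length mismatch")
  A <- config$extinction * (config$separation * config$dpf)
  if (abs(det(A)) < 1e-12) stop_config("singular pathlength-weighted system")
  sol <- solve(A, rbind(dod_1, dod_2))   # mM
  list(HbO = sol[1, ] * 1000, HbR = sol[2, ] * 1000)
}
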