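# UV-visible QC for partitioning assays: protein quantification by
# baseline-corrected A280 and detection of aggregation through the
# light-scattering elevation of the long-wavelength baseline.

#' UV-visible absorbance spectrum
#'
#' @param wavelengths Wavelengths in nm, increasing; the grid must cover
#'   at least 240-400 nm with step <= 2 nm.
#' @param absorbance Absorbance (AU) at each wavelength, finite.
#' @param label Condition/time tag.
#' @return A data frame of class `uv_spectrum`.
#' @export
uv_spectrum <- function(wavelengths, absorbance, label = "") {
  if (length(wavelengths) != length(absorbance)) {
    stop("wavelengths and absorbance must have equal length", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be increasing", call. = FALSE)
  }
  if (min(wavelengths) > 240 || max(wavelengths) < 400) {
    stop("spectrum must cover at least 240-400 nm", call. = FALSE)
  }
  if (max(diff(wavelengths)) > 2) {
    stop("wavelength grid step must be <= 2 nm", call. = FALSE)
  }
  if (any(!is.finite(absorbance))) {
    stop("absorbance must be finite", call. = FALSE)
  }
  out <- data.frame(wavelength_nm = wavelengths, absorbance_au = absorbance)
  attr(out, "label") <- label
  class(out) <- c("uv_spectrum", "data.frame")
  out
}

# linear interpolation readout at a single wavelength
.abs_at <- function(spec, wl) {
  if (wl < min(spec$wavelength_nm) || wl > max(spec$wavelength_nm)) {
    stop(sprintf("spectrum does not cover %g nm", wl), call. = FALSE)
  }
  stats::approx(spec$wavelength_nm, spec$absorbance_au, xout = wl)$y
}

#' Baseline-corrected protein absorbance
#'
#' The standard drift correction A(280) - A(350): the 350 nm reading is
#' attributed to instrumental baseline (plus any flat scatter) and
#' subtracted from the aromatic band. Note that for curved (power-law)
#' scatter this two-point correction under-subtracts the scatter present
#' at 280 nm; use [scatter_profile()] to diagnose that case.
#'
#' @param spec A [uv_spectrum()] covering 280 and 350 nm.
#' @return Corrected A280 in AU.
#' @export
baseline_corrected_a280 <- function(spec) {
  stopifnot(inherits(spec, "uv_spectrum"))
  .abs_at(spec, 280) - .abs_at(spec, 350)
}

#' Power-law characterization of the scattering baseline
#'
#' Fits log A = log c - beta * log(lambda) over a protein-absorbance-free
#' window (default 320-400 nm). Rayleigh scattering by small particles
#' gives beta close to 4. If any windowed absorbance is non-positive the
#' result is flagged as no-scatter (beta undefined, amplitude 0) rather
#' than an error.
#'
#' @param spec A [uv_spectrum()].
#' @param window Length-2 nm range used for the log-log fit.
#' @return A list with `scatter_exponent` (beta), `amplitude` (c), and
#'   `no_scatter` flag.
#' @export
scatter_profile <- function(spec, window = c(320, 400)) {
  stopifnot(inherits(spec, "uv_spectrum"), length(window) == 2)
  sel <- spec$wavelength_nm >= window[1] & spec$wavelength_nm <= window[2]
  wl <- spec$wavelength_nm[sel]
  ab <- spec$absorbance_au[sel]
  if (length(wl) < 3) {
    stop("scatter window contains fewer than 3 grid points", call. = FALSE)
  }
  if (any(ab <= 0)) {
    return(list(scatter_exponent = NA_real_, amplitude = 0,
                no_scatter = TRUE))
  }
  fit <- stats::lm(log(ab) ~ log(wl))
  cf <- stats::coef(fit)
  list(scatter_exponent = -unname(cf[2]),
       amplitude = exp(unname(cf[1])),
       no_scatter = FALSE)
}

#' Aggregation index: baseline elevation at 350 nm
#'
#' Light scattering by growing aggregates elevates the entire absorbance
#' baseline; the change at 350 nm (where the protein itself does not
#' absorb) between a later spectrum and the time-zero reference measures
#' that elevation.
#'
#' @param spec_t Spectrum at the later time point.
#' @param spec_0 Reference (time-zero) spectrum.
#' @param threshold Classification threshold in AU (default 0.01):
#'   indices above it are called "aggregating".
#' @return A list with `delta_a350` (AU) and logical `aggregating`.
#' @export
aggregation_index <- function(spec_t, spec_0, threshold = 0.01) {
  stopifnot(inherits(spec_t, "uv_spectrum"), inherits(spec_0, "uv_spectrum"))
  d <- .abs_at(spec_t, 350) - .abs_at(spec_0, 350)
  list(delta_a350 = d, aggregating = d > threshold)
}
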