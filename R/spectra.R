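#' Construct a spectrum
#'
#' A spectrum is a wavelength-gridded table of either molar absorptivity
#' (absorption kind, in L mol^-1 cm^-1) or emission intensity (emission
#' kind, arbitrary units) on a strictly increasing wavelength grid in nm.
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param values non-negative numeric vector, same length as
#'   `wavelengths`.
#' @param kind `"absorption"` or `"emission"`.
#' @return An object of class `spectrum`: a data frame with columns
#'   `wavelength_nm` and `value` plus a `kind` attribute.
#' @examples
#' sp <- spectrum(seq(400, 520, 1), dnorm(seq(400, 520, 1), 457, 20))
#' @export
spectrum <- function(wavelengths, values, kind = c("absorption", "emission")) {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) < 2L) stop("spectrum grid must have length >= 2")
  if (length(values) != length(wavelengths))
    stop("wavelengths and values must have the same length")
  if (anyNA(wavelengths) || anyNA(values)) stop("spectrum contains NA")
  if (any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing (no duplicates)")
  if (any(values < 0)) stop("spectrum values must be non-negative")
  out <- data.frame(wavelength_nm = wavelengths, value = values)
  attr(out, "kind") <- kind
  class(out) <- c("spectrum", "data.frame")
  out
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum: %s, %d points, %.1f-%.1f nm, peak %.4g at %.1f nm>\n",
    attr(x, "kind"), nrow(x), min(x$wavelength_nm), max(x$wavelength_nm),
    max(x$value), x$wavelength_nm[which.max(x$value)]
  ))
  invisible(x)
}

#' Read / write a spectrum as two-column CSV
#'
#' The dialect is a headered CSV with columns `wavelength_nm,value`.
#'
#' @param path file path.
#' @param kind spectrum kind for the object returned by the reader.
#' @return `read_spectrum` returns a [spectrum()]; `write_spectrum`
#'   returns the path invisibly.
#' @export
read_spectrum <- function(path, kind = c("absorption", "emission")) {
  kind <- match.arg(kind)
  tab <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(tab)))
    stop("spectrum CSV requires columns 'wavelength_nm' and 'value': ", path)
  spectrum(tab$wavelength_nm, tab$value, kind = kind)
}

#' @rdname read_spectrum
#' @param sp a [spectrum()].
#' @export
write_spectrum <- function(sp, path) {
  utils::write.csv(
    data.frame(wavelength_nm = sp$wavelength_nm, value = sp$value),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

# Linear interpolation of a spectrum onto an arbitrary grid; zero outside
# its support (spectra vanish outside the measured window).
interp_spectrum <- function(sp, grid) {
  stats::approx(sp$wavelength_nm, sp$value, xout = grid,
                yleft = 0, yright = 0)$y
}

#' Gaussian model spectrum
#'
#' A single Gaussian band, the shape used throughout the synthetic data
#' to emulate DCM-like absorption (max near 457 nm) and emission (max
#' near 590 nm) bands.
#'
#' @param center peak wavelength, nm.
#' @param fwhm full width at half maximum, nm (> 0).
#' @param peak peak value (absorptivity or intensity).
#' @param grid wavelength grid, nm.
#' @inheritParams spectrum
#' @return A [spectrum()].
#' @export
gaussian_spectrum <- function(center, fwhm, peak, grid,
                              kind = c("absorption", "emission")) {
  if (fwhm <= 0) stop("fwhm must be > 0")
  vals <- peak * exp(-4 * log(2) * (grid - center)^2 / fwhm^2)
  spectrum(grid, vals, kind = match.arg(kind))
}
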