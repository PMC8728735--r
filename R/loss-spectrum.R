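#' Dielectric loss spectrum at one temperature
#'
#' The atomic input of the dielectric pipeline: dielectric loss
#' (imaginary permittivity, dimensionless) versus frequency, measured
#' isothermally.
#'
#' @param temperature Measurement temperature in kelvin.
#' @param frequency Frequencies in Hz, strictly increasing and positive.
#' @param loss Dielectric loss values, same length as `frequency`, all finite.
#' @param label Free-text sample label (e.g. `"vitrified"`, `"cryomilled"`).
#'
#' @return An object of class `"loss_spectrum"`: a list with fields
#'   `temperature`, `frequency`, `loss`, `label`.
#' @seealso [spectrum_set()], [fit_hn()], [fit_kww()]
#' @export
loss_spectrum <- function(temperature, frequency, loss, label = "") {
  check_scalar(temperature, "temperature", lower = 0, open_lower = TRUE)
  if (length(frequency) != length(loss)) {
    amk_format_error("`frequency` and `loss` must have the same length")
  }
  if (any(!is.finite(frequency)) || any(frequency <= 0)) {
    amk_domain_error("frequencies must be finite and positive")
  }
  if (any(diff(frequency) <= 0)) {
    amk_format_error("frequencies must be strictly increasing")
  }
  if (any(!is.finite(loss))) {
    amk_domain_error("all loss values must be finite")
  }
  structure(
    list(temperature = as.numeric(temperature),
         frequency = as.numeric(frequency),
         loss = as.numeric(loss),
         label = as.character(label)[1]),
    class = "loss_spectrum"
  )
}

#' @export
print.loss_spectrum <- function(x, ...) {
  cat(sprintf(
    "<loss_spectrum> T = %.2f K, %d points, %.1e-%.1e Hz%s\n",
    x$temperature, length(x$frequency), min(x$frequency), max(x$frequency),
    if (nzchar(x$label)) paste0(", label: ", x$label) else ""))
  invisible(x)
}

# Eligibility for nonlinear fitting: enough points and frequency leverage.
is_fit_eligible <- function(spectrum, min_points = 8L, min_decades = 2) {
  n <- length(spectrum$frequency)
  span <- log10(max(spectrum$frequency) / min(spectrum$frequency))
  n >= min_points && span >= min_decades
}

#' Ordered collection of loss spectra
#'
#' Bundles one [loss_spectrum()] per temperature, sorted by ascending
#' temperature.  Temperatures must be unique.
#'
#' @param spectra A list of [loss_spectrum()] objects.
#' @param metadata Optional named list of instrument/sample descriptors.
#'
#' @return An object of class `"spectrum_set"`.
#' @export
spectrum_set <- function(spectra, metadata = list()) {
  if (!is.list(spectra) || length(spectra) == 0 ||
      !all(vapply(spectra, inherits, TRUE, "loss_spectrum"))) {
    amk_format_error("`spectra` must be a non-empty list of loss_spectrum objects")
  }
  temps <- vapply(spectra, `[[`, 0.0, "temperature")
  if (anyDuplicated(temps)) {
    amk_format_error("temperatures in a spectrum_set must be unique")
  }
  structure(
    list(spectra = spectra[order(temps)], metadata = metadata),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  temps <- temperatures(x)
  cat(sprintf("<spectrum_set> %d spectra, %.2f-%.2f K\n",
              length(x$spectra), min(temps), max(temps)))
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) length(x$spectra)

#' Temperatures of a spectrum set
#'
#' @param x A [spectrum_set()].
#' @return Numeric vector of temperatures in kelvin, ascending.
#' @export
temperatures <- function(x) {
  vapply(x$spectra, `[[`, 0.0, "temperature")
}

# Extract the spectrum measured at (or nearest to) a temperature.
spectrum_at <- function(set, temperature, tol = 1e-6) {
  temps <- temperatures(set)
  i <- which.min(abs(temps - temperature))
  if (abs(temps[i] - temperature) > tol) {
    amk_domain_error(sprintf("no spectrum at T = %g K (nearest: %g K)",
                             temperature, temps[i]))
  }
  set$spectra[[i]]
}

# Does the loss curve contain an interior alpha peak (as opposed to a
# flank-only, sub-Tg spectrum)?  Looks for a local maximum of the lightly
# smoothed log-loss away from the window edges.
find_loss_peak <- function(spectrum, edge = 1L, smooth = 3L) {
  y <- log10(pmax(spectrum$loss, .Machine$double.xmin))
  n <- length(y)
  if (n >= smooth + 2L && smooth > 1L) {
    ys <- stats::filter(y, rep(1 / smooth, smooth), sides = 2)
    y <- ifelse(is.na(ys), y, as.numeric(ys))
  }
  interior <- seq(edge + 1L, n - edge)
  locmax <- interior[vapply(interior, function(i) {
    y[i] >= y[i - 1L] && y[i] >= y[i + 1L]
  }, TRUE)]
  if (length(locmax) == 0) return(NULL)
  i <- locmax[which.max(y[locmax])]
  list(index = i, frequency = spectrum$frequency[i], loss = spectrum$loss[i])
}
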