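#' Sampled optical spectrum
#'
#' Container for an emission or molar-extinction spectrum sampled on a
#' strictly increasing wavelength grid (nm). Emission values are in
#' arbitrary units; extinction values are molar extinction coefficients in
#' M^-1 cm^-1 and must be nonnegative.
#'
#' @param wavelengths Numeric, strictly increasing wavelength grid (nm).
#' @param values Numeric intensities, same length as `wavelengths`.
#' @param kind Either `"emission"` or `"extinction"`.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, values, kind = c("emission", "extinction")) {
  kind <- match.arg(kind)
  stop_if(length(wavelengths) == 0L, "empty wavelength grid")
  stop_if(length(wavelengths) != length(values),
          "wavelengths and values differ in length")
  stop_if(any(diff(wavelengths) <= 0), "wavelength grid must be strictly increasing")
  stop_if(kind == "extinction" && any(values < 0),
          "extinction values must be nonnegative")
  structure(list(wavelengths = as.numeric(wavelengths),
                 values = as.numeric(values), kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %.0f-%.0f nm>\n", x$kind,
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

# Linear interpolation onto a new grid; zero outside the support.
interp_spectrum <- function(s, grid) {
  stats::approx(s$wavelengths, s$values, xout = grid, rule = 1)$y -> v
  v[is.na(v)] <- 0
  v
}

#' Fluorophore description for the synthetic generators
#'
#' A fluorophore is described by Gaussian vibronic bands for its emission and
#' extinction spectra, its fluorescence quantum yield, and its unquenched
#' lifetime. Peaks are rows of `(center_nm, width_nm, height)`; extinction
#' heights are peak molar extinction coefficients (M^-1 cm^-1).
#'
#' @param name Label.
#' @param emission_peaks Matrix-like with columns center, width, height.
#' @param extinction_peaks Same shape; heights in M^-1 cm^-1.
#' @param quantum_yield Fraction in \[0, 1\].
#' @param lifetime Fluorescence lifetime (ns), > 0.
#' @return Object of class `fluorophore_spec`.
#' @export
fluorophore_spec <- function(name, emission_peaks, extinction_peaks,
                             quantum_yield, lifetime) {
  em <- peak_matrix(emission_peaks)
  ex <- peak_matrix(extinction_peaks)
  for (m in list(em, ex)) {
    if (nrow(m)) {
      stop_if(any(m[, 2] <= 0), "peak widths must be > 0")
      stop_if(any(m[, 3] < 0), "peak heights must be >= 0")
    }
  }
  stop_if(quantum_yield < 0 || quantum_yield > 1, "quantum_yield must be in [0, 1]")
  stop_if(lifetime <= 0, "lifetime must be > 0")
  structure(list(name = name, emission_peaks = em, extinction_peaks = ex,
                 quantum_yield = quantum_yield, lifetime = lifetime),
            class = "fluorophore_spec")
}

peak_matrix <- function(p) {
  if (is.null(p) || (is.list(p) && length(p) == 0L)) {
    return(matrix(numeric(0), ncol = 3))
  }
  if (is.list(p) && !is.data.frame(p)) p <- do.call(rbind, p)
  m <- as.matrix(p)
  stop_if(ncol(m) != 3, "peaks need columns (center, width, height)")
  unname(m)
}

#' Build emission and extinction spectra from a fluorophore description
#'
#' Each spectrum is a sum of Gaussian bands evaluated on the grid. The
#' emission spectrum is normalized to unit area (trapezoid rule); the
#' extinction spectrum keeps absolute molar units.
#'
#' @param spec A [fluorophore_spec()].
#' @param grid Strictly increasing wavelength grid (nm).
#' @return List with elements `emission` and `extinction`, both [spectrum()]s.
#' @export
make_spectra <- function(spec, grid) {
  stop_if(length(grid) == 0L, "empty grid")
  stop_if(any(diff(grid) <= 0), "grid must be strictly increasing")
  gauss_sum <- function(peaks) {
    v <- numeric(length(grid))
    if (nrow(peaks)) {
      for (i in seq_len(nrow(peaks))) {
        v <- v + peaks[i, 3] * exp(-(grid - peaks[i, 1])^2 / (2 * peaks[i, 2]^2))
      }
    }
    v
  }
  em <- gauss_sum(spec$emission_peaks)
  area <- if (length(grid) > 1) pracma::trapz(grid, em) else 0
  if (area > 0) em <- em / area
  list(emission = spectrum(grid, em, "emission"),
       extinction = spectrum(grid, gauss_sum(spec$extinction_peaks), "extinction"))
}

#' Default donor fluorophore (DPH-like polyene)
#'
#' Vibronic emission band centered near 450 nm and an absorption band around
#' 352 nm, a 15.9 ns lifetime and high quantum yield in a hydrophobic
#' channel, emulating 1,6-diphenyl-1,3,5-hexatriene bound inside a barrel.
#'
#' @return A [fluorophore_spec()].
#' @export
dph_fluorophore <- function() {
  fluorophore_spec(
    name = "DPH",
    emission_peaks = rbind(c(430, 11, 0.85), c(452, 13, 1.00), c(483, 16, 0.55)),
    extinction_peaks = rbind(c(332, 10, 5.5e4), c(352, 11, 8.0e4), c(371, 12, 6.0e4)),
    quantum_yield = 0.8, lifetime = 15.9)
}

#' Default acceptor fluorophore (Nile-red-like solvatochrome)
#'
#' Single broad emission band near 593 nm and a broad visible absorption band
#' overlapping the donor emission, a 4.1 ns lifetime, emulating Nile red in
#' a hydrophobic channel.
#'
#' @return A [fluorophore_spec()].
#' @export
nile_red_fluorophore <- function() {
  fluorophore_spec(
    name = "Nile red",
    emission_peaks = rbind(c(593, 32, 1.0)),
    extinction_peaks = rbind(c(552, 38, 4.5e4), c(480, 30, 1.1e4)),
    quantum_yield = 0.7, lifetime = 4.10)
}
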