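#' Spectral overlap integral
#'
#' Computes the donor-acceptor overlap integral
#' \deqn{J = \int \bar F_D(\lambda)\, \varepsilon_A(\lambda)\, \lambda^4\, d\lambda}
#' in the wavelength domain, with the donor emission spectrum area-normalized
#' on its own grid. Quadrature is trapezoidal on the union of the two grids
#' with linear interpolation (zero outside each spectrum's support).
#'
#' @param donor_emission [spectrum()] of kind `"emission"`.
#' @param acceptor_extinction [spectrum()] of kind `"extinction"`
#'   (M^-1 cm^-1).
#' @return Overlap integral J in M^-1 cm^-1 nm^4. Returns 0 with a warning
#'   when the supports are disjoint.
#' @export
overlap_integral <- function(donor_emission, acceptor_extinction) {
  stop_if(donor_emission$kind != "emission",
          "donor spectrum must be of kind 'emission'")
  stop_if(acceptor_extinction$kind != "extinction",
          "acceptor spectrum must be of kind 'extinction'")
  lo <- max(min(donor_emission$wavelengths), min(acceptor_extinction$wavelengths))
  hi <- min(max(donor_emission$wavelengths), max(acceptor_extinction$wavelengths))
  if (lo >= hi) {
    warning("disjoint spectral supports: overlap integral is 0")
    return(0)
  }
  grid <- sort(unique(c(donor_emission$wavelengths, acceptor_extinction$wavelengths)))
  grid <- grid[grid >= lo & grid <= hi]
  fd <- interp_spectrum(donor_emission, grid)
  # area-normalize the donor on its full grid, not just the overlap window
  area <- pracma::trapz(donor_emission$wavelengths, donor_emission$values)
  stop_if(area <= 0, "donor emission spectrum has zero area")
  fd <- fd / area
  ea <- interp_spectrum(acceptor_extinction, grid)
  pracma::trapz(grid, fd * ea * grid^4)
}

#' Forster radius from photophysical parameters
#'
#' \eqn{R_0^6 = 8.79\times 10^{-5}\, \kappa^2\, n^{-4}\, Q_D\, J} with J in
#' M^-1 cm^-1 nm^4 yields \eqn{R_0} in Angstrom; the return value is in nm.
#' All arguments vectorize, so passing e.g. `kappa_squared = c(lo, hi)`
#' returns the corresponding radius interval.
#'
#' @param J Overlap integral (M^-1 cm^-1 nm^4), >= 0.
#' @param kappa_squared Orientation factor in \[0, 4\]; 2/3 is the isotropic
#'   dynamic-averaging limit.
#' @param refractive_index Medium refractive index (>= 1); 1.4 is the usual
#'   protein-interior convention.
#' @param donor_quantum_yield Donor quantum yield in \[0, 1\].
#' @return Forster radius R0 in nm.
#' @export
forster_radius <- function(J, kappa_squared = 2 / 3, refractive_index = 1.4,
                           donor_quantum_yield = 1) {
  stop_if(any(J < 0), "J must be >= 0")
  stop_if(any(kappa_squared < 0 | kappa_squared > 4),
          "kappa_squared must be in [0, 4]")
  stop_if(any(refractive_index < 1), "refractive_index must be >= 1")
  stop_if(any(donor_quantum_yield < 0 | donor_quantum_yield > 1),
          "donor_quantum_yield must be in [0, 1]")
  r0_A6 <- 8.79e-5 * kappa_squared * refractive_index^-4 * donor_quantum_yield * J
  r0_A6^(1 / 6) / 10
}

#' Transfer efficiency at a given donor-acceptor distance
#'
#' \eqn{E = 1 / (1 + (r/R_0)^6)}.
#'
#' @param r Distance (nm), > 0. Vectorized.
#' @param R0 Forster radius (nm), > 0.
#' @return Efficiency in (0, 1).
#' @export
efficiency_from_distance <- function(r, R0) {
  stop_if(any(r <= 0) || any(R0 <= 0), "r and R0 must be > 0")
  1 / (1 + (r / R0)^6)
}

#' Donor-acceptor distance from a measured transfer time constant
#'
#' Inverts \eqn{k_T = (1/\tau_D)(R_0/r)^6} with \eqn{k_T = 1/\tau_T}, giving
#' \eqn{r = R_0 (\tau_T / \tau_D)^{1/6}}. Vectorized over all arguments, so a
#' `kappa^2`-derived interval of `R0` maps to a distance interval.
#'
#' @param transfer_time FRET time constant tau_T (ns), > 0.
#' @param donor_lifetime Unquenched donor lifetime tau_D (ns), > 0.
#' @param R0 Forster radius (nm), > 0.
#' @return Distance r in nm.
#' @export
distance_from_rate <- function(transfer_time, donor_lifetime, R0) {
  stop_if(any(transfer_time <= 0) || any(donor_lifetime <= 0) || any(R0 <= 0),
          "all arguments must be > 0")
  R0 * (transfer_time / donor_lifetime)^(1 / 6)
}

#' Transfer rate implied by a donor-acceptor distance
#'
#' Companion inverse of [distance_from_rate()]: returns the transfer time
#' constant \eqn{\tau_T = \tau_D (r/R_0)^6} in ns.
#'
#' @inheritParams distance_from_rate
#' @param r Distance (nm), > 0.
#' @return Transfer time constant in ns.
#' @export
rate_time_from_distance <- function(r, donor_lifetime, R0) {
  stop_if(any(r <= 0) || any(donor_lifetime <= 0) || any(R0 <= 0),
          "all arguments must be > 0")
  donor_lifetime * (r / R0)^6
}

#' Transfer efficiency from quenched and unquenched donor lifetimes
#'
#' \eqn{E = 1 - \tau_{DA}/\tau_D}. If `tau_DA > tau_D` the ratio is clamped
#' to 1 with a warning (efficiency 0).
#'
#' @param tau_DA Donor lifetime in presence of acceptor (ns), > 0.
#' @param tau_D Donor-only lifetime (ns), > 0.
#' @return Efficiency in \[0, 1\].
#' @export
efficiency_from_lifetimes <- function(tau_DA, tau_D) {
  stop_if(any(tau_DA <= 0) || any(tau_D <= 0), "lifetimes must be > 0")
  ratio <- tau_DA / tau_D
  if (any(ratio > 1)) {
    warning("tau_DA exceeds tau_D; efficiency clamped to 0")
    ratio <- pmin(ratio, 1)
  }
  1 - ratio
}
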