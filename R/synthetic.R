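#' Noise description for the synthetic generators
#'
#' @param kind `"poisson"` (counting statistics) or `"gaussian"`.
#' @param sigma Relative standard deviation for gaussian noise; ignored for
#'   poisson.
#' @param seed Integer RNG seed; `NULL` leaves the caller's RNG untouched.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("poisson", "gaussian"), sigma = 0, seed = 1L) {
  kind <- match.arg(kind)
  stop_if(sigma < 0, "sigma must be >= 0")
  structure(list(kind = kind, sigma = sigma, seed = seed), class = "noise_spec")
}

#' Simulate a TCSPC decay histogram with its IRF
#'
#' The expected curve is the decay model convolved with a Gaussian IRF,
#' scaled so its maximum equals `peak_counts`, plus a constant background of
#' `background_frac * peak_counts`. Counts are then drawn channelwise:
#' Poisson by default, or Gaussian with relative sigma (sigma 0 returns the
#' noiseless expectation exactly). A Gaussian IRF histogram at `t0` is
#' emitted alongside. If the window is shorter than five times the longest
#' lifetime the trace carries a `window_warning` attribute.
#'
#' @param model A [multiexp_model()] (its baseline field is ignored here;
#'   background is controlled by `background_frac`).
#' @param irf_fwhm IRF full width at half maximum (ns); default 0.170.
#' @param n_channels Number of channels (default 4096).
#' @param t_max Acquisition window (ns), channels span \[0, t_max\].
#' @param peak_counts Counts in the peak channel (>= 100).
#' @param background_frac Constant background as a fraction of the peak.
#' @param t0 Excitation time (ns) within the window.
#' @param noise A [noise_spec()].
#' @return A [decay_trace()] with `irf_sigma` set.
#' @export
simulate_tcspc <- function(model, irf_fwhm = 0.170, n_channels = 4096,
                           t_max = 100, peak_counts = 2e4,
                           background_frac = 0.01, t0 = 2,
                           noise = noise_spec("poisson", seed = 1L)) {
  stop_if(peak_counts < 100, "peak_counts must be >= 100")
  sigma <- fwhm_to_sigma(irf_fwhm)
  dt <- t_max / n_channels
  time <- (seq_len(n_channels) - 0.5) * dt
  # bypass the constructor so the degenerate all-zero-amplitude case (an
  # all-background trace) is representable
  m <- structure(list(amplitudes = model$amplitudes,
                      lifetimes = model$lifetimes,
                      baseline = 0, t0_shift = t0),
                 class = "multiexp_model")
  curve <- convolve_model(m, time, sigma)
  if (max(curve) > 0) curve <- curve / max(curve) * peak_counts
  expected <- curve + background_frac * peak_counts
  counts <- with_seed(noise$seed, draw_counts(expected, noise))
  irf <- exp(-(time - t0)^2 / (2 * sigma^2))
  irf <- irf / max(irf) * peak_counts
  tr <- decay_trace(time, counts, irf_counts = irf, irf_sigma = sigma)
  if (t_max - t0 < 5 * max(model$lifetimes)) {
    attr(tr, "window_warning") <- TRUE
    warning("acquisition window shorter than 5x the longest lifetime")
  }
  tr
}

draw_counts <- function(expected, noise) {
  if (noise$kind == "poisson") {
    rpois(length(expected), expected)
  } else if (noise$sigma == 0) {
    expected
  } else {
    expected * (1 + rnorm(length(expected), 0, noise$sigma))
  }
}

#' Two-population energy-transfer scheme for target analysis
#'
#' The kinetic model has an excited donor split into a dominant fast-transfer
#' subpopulation (fraction `f_fast`, time constant `tau_fast_ps`) and a
#' minority slow-transfer subpopulation (`tau_slow_ns`), both also decaying
#' radiatively at the donor rate; the acceptor is fed by both branches and
#' decays at its own rate. Rates are stored internally in ps^-1.
#'
#' @param tau_fast_ps Fast transfer time constant (ps).
#' @param tau_slow_ns Slow transfer time constant (ns).
#' @param tau_donor_ns Donor radiative lifetime (ns).
#' @param tau_acceptor_ns Acceptor lifetime (ns).
#' @param f_fast Fraction of donors on the fast pathway, in \[0, 1\].
#' @param excited_species `"donor"` or `"acceptor"` (direct-excitation
#'   control).
#' @return Object of class `target_scheme` with rate fields `k_fast`,
#'   `k_slow`, `k_donor`, `k_acceptor` (all ps^-1).
#' @export
target_scheme <- function(tau_fast_ps = 10.4, tau_slow_ns = 0.98,
                          tau_donor_ns = 15.9, tau_acceptor_ns = 4.9,
                          f_fast = 0.95,
                          excited_species = c("donor", "acceptor")) {
  excited_species <- match.arg(excited_species)
  stop_if(any(c(tau_fast_ps, tau_slow_ns, tau_donor_ns, tau_acceptor_ns) < 0),
          "time constants must be >= 0")
  stop_if(f_fast < 0 || f_fast > 1, "f_fast must be in [0, 1]")
  inv <- function(x) if (x > 0) 1 / x else 0
  structure(list(k_fast = inv(tau_fast_ps),
                 k_slow = inv(tau_slow_ns * 1000),
                 k_donor = inv(tau_donor_ns * 1000),
                 k_acceptor = inv(tau_acceptor_ns * 1000),
                 f_fast = f_fast, excited_species = excited_species),
            class = "target_scheme")
}

#' Scheme parameterized at the heptamer reference values
#' @return A [target_scheme()].
#' @export
heptamer_scheme <- function() {
  target_scheme(tau_fast_ps = 10.4, tau_slow_ns = 0.98, tau_donor_ns = 15.9,
                tau_acceptor_ns = 4.9, f_fast = 0.95)
}

#' Scheme parameterized at the octamer reference values
#' @return A [target_scheme()].
#' @export
octamer_scheme <- function() {
  target_scheme(tau_fast_ps = 7.9, tau_slow_ns = 1.3, tau_donor_ns = 15.8,
                tau_acceptor_ns = 5.1, f_fast = 0.95)
}

#' Default pump-probe delay grid
#'
#' Linear from -1 to +1 ps then logarithmic out to `t_end_ps` (default 7 ns),
#' the usual pump-probe practice.
#'
#' @param t_end_ps Last delay (ps).
#' @param n_linear,n_log Point counts for the two segments.
#' @return Numeric delays (ps).
#' @export
default_delays <- function(t_end_ps = 7000, n_linear = 41, n_log = 80) {
  c(seq(-1, 1, length.out = n_linear),
    exp(seq(log(1.05), log(t_end_ps), length.out = n_log)))
}

#' Simulate a transient-absorption map
#'
#' \eqn{\Delta mOD(t, \lambda) = \sum_s pop_s(t)\, S_s(\lambda)} plus
#' Gaussian noise (relative to the global maximum absolute signal).
#' Stimulated-emission species spectra are negative-valued by convention.
#'
#' @param scheme A [target_scheme()].
#' @param species_spectra List of two [spectrum()]s (donor, acceptor signal
#'   spectra, in ΔmOD units per unit population).
#' @param delays Delay grid (ps); must include at least one pre-zero point.
#' @param irf_fwhm_ps IRF FWHM (ps); default 0.28.
#' @param noise A [noise_spec()] of kind gaussian (sigma relative to the
#'   absolute signal maximum).
#' @return Object of class `ta_map` with `delays`, `wavelengths`,
#'   `delta_mOD` (delays x wavelengths matrix).
#' @export
simulate_ta <- function(scheme, species_spectra, delays = default_delays(),
                        irf_fwhm_ps = 0.28,
                        noise = noise_spec("gaussian", sigma = 0.01, seed = 1L)) {
  stop_if(!any(delays < 0), "delay grid must include a pre-zero baseline point")
  stop_if(length(species_spectra) != 2,
          "need exactly two species spectra (donor, acceptor)")
  grids <- vapply(species_spectra, function(s) length(s$wavelengths), 1L)
  wl <- species_spectra[[1]]$wavelengths
  stop_if(!all(vapply(species_spectra,
                      function(s) isTRUE(all.equal(s$wavelengths, wl)), TRUE)),
          "species spectra must share a wavelength grid")
  pops <- solve_populations(scheme, delays, fwhm_to_sigma(irf_fwhm_ps))
  S <- rbind(species_spectra[[1]]$values, species_spectra[[2]]$values)
  map <- pops %*% S
  if (noise$kind == "gaussian" && noise$sigma > 0) {
    amp <- max(abs(map))
    map <- map + with_seed(noise$seed,
                           matrix(rnorm(length(map), 0, noise$sigma * amp),
                                  nrow = nrow(map)))
  }
  structure(list(delays = delays, wavelengths = wl, delta_mOD = map),
            class = "ta_map")
}

#' Simulate a saturation binding titration
#'
#' Single-site binding with explicit ligand depletion: the bound complex is
#' the quadratic root of the mass-balance system, appropriate when ligand
#' and Kd are comparable. The observable is
#' \eqn{F/F_{max} = f_0 + (1 - f_0)\, bound fraction} plus relative Gaussian
#' noise.
#'
#' @param kd Dissociation constant (uM), > 0.
#' @param ligand_total Total ligand (uM); default 0.5.
#' @param peptide_grid Peptide-assembly concentrations (uM); default 12
#'   points over 0-30.
#' @param f0 Baseline normalized fluorescence of free dye.
#' @param noise A [noise_spec()] (gaussian, relative).
#' @param replicates Replicate count sharing the grid.
#' @return Object of class `binding_series`: data.frame with `conc_uM`,
#'   `f_norm`, `replicate`, plus `ligand_total` attribute.
#' @export
simulate_titration <- function(kd, ligand_total = 0.5,
                               peptide_grid = c(0, 0.5, 1, 2, 3, 5, 7.5, 10,
                                                15, 20, 25, 30),
                               f0 = 0.05,
                               noise = noise_spec("gaussian", sigma = 0,
                                                  seed = 1L),
                               replicates = 1L) {
  stop_if(kd <= 0, "kd must be > 0")
  stop_if(any(peptide_grid < 0), "peptide concentrations must be >= 0")
  fb <- bound_fraction_depletion(peptide_grid, ligand_total, kd)
  f <- f0 + (1 - f0) * fb
  df <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    fr <- f
    if (noise$kind == "gaussian" && noise$sigma > 0) {
      fr <- with_seed(noise$seed + r - 1L,
                      f * (1 + rnorm(length(f), 0, noise$sigma)))
    }
    data.frame(conc_uM = peptide_grid, f_norm = fr, replicate = r)
  }))
  structure(df, ligand_total = ligand_total, class = c("binding_series",
                                                       "data.frame"))
}

# Fraction of ligand bound under single-site binding with depletion.
bound_fraction_depletion <- function(P, L, Kd) {
  if (L <= 0) return(rep(0, length(P)))
  s <- P + L + Kd
  C <- (s - sqrt(s^2 - 4 * P * L)) / 2
  C / L
}

#' Simulate a 1D free-energy profile over inter-dye distance
#'
#' Profile = sum of negative Gaussian wells plus spatially correlated
#' Gaussian noise (white noise smoothed with a Gaussian kernel of
#' `noise_corr_A` correlation length, then rescaled to `noise_std`),
#' emulating the smooth sampling error of a converged biased-sampling
#' estimate rather than point-wise scatter. A constant
#' standard-deviation band accompanies the curve.
#'
#' @param wells List of `c(center_A, depth_kJ_mol, width_A)` triples; depth
#'   is the positive well magnitude.
#' @param range Distance interval (Angstrom); default 1.5-40.
#' @param n_points Grid size.
#' @param noise_std Gaussian noise std (kJ/mol).
#' @param noise_corr_A Noise correlation length (Angstrom).
#' @param seed RNG seed.
#' @return Object of class `fes_profile`: list with `distance`,
#'   `free_energy`, `std`.
#' @export
simulate_fes <- function(wells, range = c(1.5, 40), n_points = 400,
                         noise_std = 1, noise_corr_A = 1, seed = 1L) {
  centers <- vapply(wells, `[`, 1, FUN.VALUE = 1)
  stop_if(length(centers) > 0 &&
            (any(centers < range[1]) || any(centers > range[2])),
          "well centers must lie inside the range")
  d <- seq(range[1], range[2], length.out = n_points)
  F <- numeric(n_points)
  for (w in wells) F <- F - w[2] * exp(-(d - w[1])^2 / (2 * w[3]^2))
  if (noise_std > 0) {
    F <- F + with_seed(seed, {
      white <- rnorm(n_points)
      dx <- d[2] - d[1]
      half <- ceiling(3 * noise_corr_A / dx)
      kern <- dnorm(seq(-half, half) * dx, 0, noise_corr_A)
      sm <- as.numeric(stats::filter(c(rev(white[seq_len(half)]), white,
                                       rev(tail(white, half))),
                                     kern / sum(kern), sides = 2))
      sm <- sm[half + seq_len(n_points)]
      sm / stats::sd(sm) * noise_std
    })
  }
  free_energy_profile(d, F, std = rep(noise_std, n_points))
}

#' Reference heptamer free-energy wells
#'
#' Deep minima at 3.5 and 10.0 Angstrom (depths 93 and 92 kJ/mol) plus a
#' shallow shelf near 25 Angstrom; widths are the generator's own choice.
#' @return List of well triples for [simulate_fes()].
#' @export
heptamer_fes_wells <- function() {
  list(c(3.5, 93, 0.8), c(10.0, 92, 1.5), c(25, 8, 3))
}

#' Reference octamer free-energy wells
#'
#' Broad global minimum at 4.1 Angstrom (94.6 kJ/mol) and a shallower
#' minimum near 20 Angstrom.
#' @return List of well triples for [simulate_fes()].
#' @export
octamer_fes_wells <- function() {
  list(c(4.1, 94.6, 1.6), c(20, 70, 2.5))
}

#' Simulate an irradiation time course
#'
#' Promoted photodimerization follows
#' \eqn{F(t) = p + (1 - p) e^{-k t}}; inhibited follows a slow linear drift
#' \eqn{F(t) = 1 - s t} clipped at 0. Relative Gaussian noise is added.
#'
#' @param mode `"promoted"` or `"inhibited"`.
#' @param rate Rate k (min^-1) for promoted, slope s (fraction/min) for
#'   inhibited; >= 0.
#' @param duration Duration (min), > 0; default 30.
#' @param n_points Number of samples (including t = 0).
#' @param plateau Residual fluorescence plateau p for promoted mode.
#' @param noise A [noise_spec()] (gaussian, relative).
#' @param label Sample id.
#' @return Object of class `time_course`: data.frame `time_min`, `f_norm`.
#' @export
simulate_photolysis <- function(mode = c("promoted", "inhibited"), rate,
                                duration = 30, n_points = 16, plateau = 0.02,
                                noise = noise_spec("gaussian", sigma = 0,
                                                   seed = 1L),
                                label = mode) {
  mode <- match.arg(mode)
  stop_if(rate < 0, "rate must be >= 0")
  stop_if(duration <= 0, "duration must be > 0")
  t <- seq(0, duration, length.out = n_points)
  f <- if (mode == "promoted") {
    plateau + (1 - plateau) * exp(-rate * t)
  } else {
    pmax(1 - rate * t, 0)
  }
  if (noise$kind == "gaussian" && noise$sigma > 0) {
    f <- with_seed(noise$seed, f + rnorm(n_points, 0, noise$sigma))
  }
  time_course(t, f, label = label[1])
}

#' Default synthetic FRET screen fixture
#'
#' Builds a 15-panel screen in which a chosen number of panels are
#' constructed FRET-positive. Each panel holds donor-only, acceptor-only and
#' mixed emission spectra; the mixed spectrum is built from a known transfer
#' fraction E so that the apparent-efficiency estimator should return E.
#' Negative panels use transfer fractions well below the screening threshold.
#'
#' @param n_panels Total panels (default 15).
#' @param n_positive Constructed positives (default 10).
#' @param positive_e Transfer fractions for positives.
#' @param negative_e Transfer fractions for negatives.
#' @param noise_sigma Relative Gaussian noise added to each spectrum.
#' @param seed RNG seed.
#' @return List of panels `(peptide_id, donor_only, acceptor_only, mixed)`
#'   with attribute `true_positive` (logical vector) and `true_e`.
#' @export
simulate_screen_panels <- function(n_panels = 15, n_positive = 10,
                                   positive_e = seq(0.25, 0.85,
                                                    length.out = n_positive),
                                   negative_e = rep(0.01,
                                                    n_panels - n_positive),
                                   noise_sigma = 0.005, seed = 1L) {
  stop_if(n_positive > n_panels, "n_positive exceeds n_panels")
  grid <- seq(380, 720, by = 1)
  donor <- make_spectra(dph_fluorophore(), grid)$emission
  acceptor_em <- make_spectra(nile_red_fluorophore(), grid)$emission
  e_true <- numeric(n_panels)
  pos_idx <- seq_len(n_positive)
  e_true[pos_idx] <- positive_e
  if (n_panels > n_positive) e_true[-pos_idx] <- negative_e
  bd <- band_area(donor, 450)
  ba <- band_area(acceptor_em, 593)
  with_seed(seed, {
    panels <- lapply(seq_len(n_panels), function(i) {
      E <- e_true[i]
      mixed_v <- (1 - E) * donor$values + (E * bd / ba) * acceptor_em$values
      jitter <- function(v) pmax(v * (1 + rnorm(length(v), 0, noise_sigma)), 0)
      list(peptide_id = sprintf("pep%02d", i),
           donor_only = spectrum(grid, jitter(donor$values), "emission"),
           acceptor_only = spectrum(grid, jitter(acceptor_em$values), "emission"),
           mixed = spectrum(grid, jitter(mixed_v), "emission"))
    })
    structure(panels, true_positive = e_true >= 0.1, true_e = e_true)
  })
}
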