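# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Discrete FFT convolution of a multi-exponential decay with a Gaussian IRF
# on a fine uniform grid, evaluated at `time`.
fft_convolve_oracle <- function(amplitudes, lifetimes, time, sigma, t0 = 0,
                                oversample = 256) {
  dt <- (time[2] - time[1]) / oversample
  pad <- 8 * sigma
  fine <- seq(min(time) - pad, max(time) + pad, by = dt)
  # cell-averaged samples (exact integrals over each cell / dt) keep the
  # discretization error of the step discontinuity at O(dt^2)
  decay <- numeric(length(fine))
  u <- fine - t0
  for (i in seq_along(lifetimes)) {
    tau <- lifetimes[i]
    lo <- pmax(u - dt / 2, 0)
    hi <- pmax(u + dt / 2, 0)
    decay <- decay + amplitudes[i] * tau * (exp(-lo / tau) - exp(-hi / tau)) / dt
  }
  # the time-zero shift already lives in the decay; the IRF kernel is
  # centered at 0
  irf <- (pnorm(fine + dt / 2, 0, sigma) - pnorm(fine - dt / 2, 0, sigma)) / dt
  n <- length(fine)
  m <- stats::nextn(2 * n)
  conv <- Re(stats::fft(stats::fft(c(decay, rep(0, m - n))) *
                        stats::fft(c(irf, rep(0, m - n))), inverse = TRUE)) / m
  conv <- conv[seq_len(n)] * dt
  # linear convolution of samples indexed from fine[1] lives on the grid
  # fine + fine[1]
  stats::approx(fine + fine[1], conv, xout = time, rule = 2)$y
}

# Stiff-ODE populations oracle for the two-population transfer scheme with a
# Gaussian excitation pulse (unit integral) at t = 0.
ode_populations_oracle <- function(scheme, delays, sigma, rtol = 1e-11) {
  testthat::skip_if_not_installed("deSolve")
  p <- list(kf = scheme$k_fast, ks = scheme$k_slow, kd = scheme$k_donor,
            ka = scheme$k_acceptor, f = scheme$f_fast,
            excited = scheme$excited_species)
  rhs <- function(t, y, p) {
    exc <- dnorm(t, 0, sigma)
    if (p$excited == "acceptor") {
      list(c(0, 0, exc - p$ka * y[3], p$ka * y[3]))
    } else {
      list(c(p$f * exc - (p$kf + p$kd) * y[1],
             (1 - p$f) * exc - (p$ks + p$kd) * y[2],
             p$kf * y[1] + p$ks * y[2] - p$ka * y[3],
             p$kd * (y[1] + y[2]) + p$ka * y[3]))
    }
  }
  start <- min(c(delays, -8 * sigma))
  times <- sort(unique(c(start, delays)))
  sol <- deSolve::ode(c(0, 0, 0, 0), times, rhs, p, method = "lsoda",
                      rtol = rtol, atol = 1e-13)
  idx <- match(delays, sol[, 1])
  cbind(donor = sol[idx, 2] + sol[idx, 3], acceptor = sol[idx, 4],
        ground = sol[idx, 5])
}

# Exhaustive basin scan: for every interior strict local minimum walk
# outward to compute prominence directly. Independent re-derivation used to
# cross-check find_basins positions.
basin_scan_oracle <- function(d, F, min_prominence) {
  n <- length(F)
  out <- numeric(0)
  for (i in 2:(n - 1)) {
    if (!(F[i] < F[i - 1] && F[i] < F[i + 1])) next
    barrier_l <- -Inf
    found_l <- FALSE
    for (j in rev(seq_len(i - 1))) {
      barrier_l <- max(barrier_l, F[j])
      if (F[j] < F[i]) { found_l <- TRUE; break }
    }
    barrier_r <- -Inf
    for (j in seq(i + 1, n)) {
      barrier_r <- max(barrier_r, F[j])
      if (F[j] < F[i]) break
    }
    prom <- min(barrier_l - F[i], barrier_r - F[i])
    if (prom >= min_prominence) out <- c(out, d[i])
  }
  out
}

# Mass-balance root-finding oracle for single-site binding with depletion.
bound_fraction_oracle <- function(P, L, Kd) {
  vapply(P, function(p) {
    if (L == 0 || p == 0) return(0)
    fn <- function(C) (p - C) * (L - C) / Kd - C
    stats::uniroot(fn, c(0, min(p, L) * (1 - 1e-12)), tol = 1e-14)$root / L
  }, 1)
}

# Competitive two-ligand equilibrium oracle: dye D (Kd_d) and competitor C
# (Kd_c) share one site; returns the bound fraction of the dye at each
# peptide concentration (total site concentration P).
competitive_bound_oracle <- function(P, D_tot, C_tot, Kd_d, Kd_c) {
  vapply(P, function(p) {
    if (p == 0) return(0)
    fn <- function(free_p) {
      bd <- D_tot * free_p / (Kd_d + free_p)
      bc <- C_tot * free_p / (Kd_c + free_p)
      free_p + bd + bc - p
    }
    free_p <- stats::uniroot(fn, c(0, p), tol = 1e-13)$root
    (D_tot * free_p / (Kd_d + free_p)) / D_tot
  }, 1)
}
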