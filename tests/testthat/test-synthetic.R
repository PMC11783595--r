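test_that("generators are pure functions of their seed", {
  m <- multiexp_model(1, 4.1)
  a <- simulate_tcspc(m, n_channels = 512, t_max = 30, peak_counts = 1000,
                      noise = noise_spec("poisson", seed = 7))
  b <- simulate_tcspc(m, n_channels = 512, t_max = 30, peak_counts = 1000,
                      noise = noise_spec("poisson", seed = 7))
  expect_identical(a$counts, b$counts)
  c_ <- simulate_tcspc(m, n_channels = 512, t_max = 30, peak_counts = 1000,
                       noise = noise_spec("poisson", seed = 8))
  expect_false(identical(a$counts, c_$counts))

  s1 <- simulate_titration(2, noise = noise_spec("gaussian", 0.02, seed = 3))
  s2 <- simulate_titration(2, noise = noise_spec("gaussian", 0.02, seed = 3))
  expect_identical(s1$f_norm, s2$f_norm)

  f1 <- simulate_fes(heptamer_fes_wells(), seed = 5)
  f2 <- simulate_fes(heptamer_fes_wells(), seed = 5)
  expect_identical(f1$free_energy, f2$free_energy)

  # the generator must not disturb the caller's RNG stream
  set.seed(42); x1 <- runif(1)
  set.seed(42)
  invisible(simulate_tcspc(m, n_channels = 256, t_max = 30,
                           peak_counts = 1000,
                           noise = noise_spec("poisson", seed = 1)))
  expect_identical(runif(1), x1)
})

test_that("Poisson channel means track the noiseless model", {
  m <- multiexp_model(1, 4.1)
  noiseless <- simulate_tcspc(m, n_channels = 256, t_max = 25,
                              peak_counts = 1000,
                              noise = noise_spec("gaussian", sigma = 0))
  n_seeds <- 200
  acc <- matrix(0, n_seeds, 256)
  for (s in seq_len(n_seeds)) {
    acc[s, ] <- simulate_tcspc(m, n_channels = 256, t_max = 25,
                               peak_counts = 1000,
                               noise = noise_spec("poisson", seed = s))$counts
  }
  mu <- colMeans(acc)
  se <- sqrt(noiseless$counts / n_seeds)
  frac_in <- mean(abs(mu - noiseless$counts) <= 3 * se)
  expect_gte(frac_in, 0.99)
})

test_that("noiseless and degenerate TCSPC traces behave exactly", {
  m <- multiexp_model(1, 4.1)
  tr <- simulate_tcspc(m, n_channels = 512, t_max = 30, peak_counts = 2000,
                       noise = noise_spec("gaussian", sigma = 0))
  model <- multiexp_model(1, 4.1, t0_shift = 2)
  conv <- convolve_model(model, tr$time, tr$irf_sigma)
  expected <- conv / max(conv) * 2000 + 0.01 * 2000
  expect_equal(tr$counts, expected, tolerance = 1e-12)

  # zero amplitude -> all-background trace
  m0 <- multiexp_model(c(0, 1e-300), c(1, 2))
  m0$amplitudes <- c(0, 0)
  tr0 <- simulate_tcspc(m0, n_channels = 256, t_max = 30, peak_counts = 1000,
                        noise = noise_spec("gaussian", sigma = 0))
  expect_true(all(tr0$counts == 10))

  # short window flags a warning
  expect_warning(
    simulate_tcspc(multiexp_model(1, 20), n_channels = 256, t_max = 30,
                   peak_counts = 1000,
                   noise = noise_spec("gaussian", sigma = 0)),
    "window")
})

test_that("titration generator matches the mass-balance root-finding oracle", {
  grid <- c(0, 0.5, 1, 2, 3, 5, 7.5, 10, 15, 20, 25, 30)
  s <- simulate_titration(2, ligand_total = 0.5, peptide_grid = grid,
                          f0 = 0.05, noise = noise_spec("gaussian", 0))
  fb_oracle <- bound_fraction_oracle(grid, 0.5, 2)
  expect_equal(s$f_norm, 0.05 + 0.95 * fb_oracle, tolerance = 1e-9)

  # no-binding limit: kd huge -> flat at f0
  flat <- simulate_titration(1e9, noise = noise_spec("gaussian", 0))
  expect_true(all(abs(flat$f_norm - 0.05) < 1e-6))

  # noiseless refit round trip
  fit <- fit_binding(s)
  expect_equal(fit$kd, 2, tolerance = 1e-6)
})

test_that("free-energy generator places wells where asked", {
  one <- simulate_fes(list(c(12, 50, 2)), noise_std = 0, seed = 1)
  expect_equal(one$distance[which.min(one$free_energy)], 12, tolerance = 0.1)
  flat <- simulate_fes(list(), noise_std = 0, seed = 1)
  expect_true(all(flat$free_energy == 0))
  hep <- simulate_fes(heptamer_fes_wells(), seed = 2)
  b <- find_basins(hep)
  expect_true(any(abs(b$position - 3.5) < 0.3))
  expect_true(any(abs(b$position - 10.0) < 0.3))
  expect_error(simulate_fes(list(c(50, 10, 1))), "inside the range")
})

test_that("photolysis generator reproduces its closed forms", {
  const <- simulate_photolysis("promoted", 0, noise = noise_spec("gaussian", 0))
  expect_true(all(abs(const$f_norm - 1) < 1e-12))

  inh <- simulate_photolysis("inhibited", 0.002, duration = 30, n_points = 16,
                             noise = noise_spec("gaussian", 0))
  expect_equal(tail(inh$f_norm, 1), 0.94, tolerance = 1e-12)

  # promoted at 0.2 / min runs to completion within 30 min
  pro <- simulate_photolysis("promoted", 0.2, duration = 30, plateau = 0.02,
                             noise = noise_spec("gaussian", 0))
  expect_lt(tail(pro$f_norm, 1) - 0.02, 0.01)
  expect_error(simulate_photolysis("promoted", 0.1, duration = -1), "duration")
})

test_that("TA generator limits match the scheme structure", {
  spectra <- ta_species_spectra()
  sig <- fwhm_to_sigma(0.28)
  # direct acceptor excitation: rise limited only by the IRF
  sc_a <- target_scheme(excited_species = "acceptor")
  map_a <- simulate_ta(sc_a, spectra, noise = noise_spec("gaussian", 0))
  kin_a <- band_kinetics(map_a)
  half <- kin_a$delays[which(abs(kin_a$signal) >=
                               max(abs(kin_a$signal[kin_a$delays > 1000])) / 2)[1]]
  expect_lt(abs(half), 5 * sig)

  # all rates zero: constant map after time zero
  sc0 <- target_scheme(tau_fast_ps = 0, tau_slow_ns = 0, tau_donor_ns = 0,
                       tau_acceptor_ns = 0)
  map0 <- simulate_ta(sc0, spectra, noise = noise_spec("gaussian", 0))
  late <- map0$delays > 2
  ref <- map0$delta_mOD[which(late)[1], ]
  for (i in which(late)) expect_equal(map0$delta_mOD[i, ], ref,
                                      tolerance = 1e-9)

  # stimulated-emission bands are negative where constructed negative
  hep <- simulate_ta(heptamer_scheme(), spectra,
                     noise = noise_spec("gaussian", 0))
  sel <- hep$wavelengths >= 575 & hep$wavelengths <= 605
  expect_true(all(hep$delta_mOD[, sel] <= 1e-12))

  # errors
  expect_error(simulate_ta(heptamer_scheme(), spectra, delays = c(1, 2)),
               "pre-zero")
  expect_error(simulate_ta(heptamer_scheme(), spectra[1]), "two species")
})

test_that("screen fixture constructs the requested positives", {
  panels <- simulate_screen_panels(seed = 11)
  expect_length(panels, 15)
  expect_identical(sum(attr(panels, "true_positive")), 10L)
  expect_true(all(attr(panels, "true_e")[attr(panels, "true_positive")] >= 0.25))
})
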