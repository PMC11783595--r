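make_ref_spectra <- function() {
  grid <- seq(380, 720, by = 1)
  list(grid = grid,
       donor = make_spectra(dph_fluorophore(), grid)$emission,
       acceptor = make_spectra(nile_red_fluorophore(), grid)$emission)
}

test_that("unmixing recovers known mixing coefficients", {
  rs <- make_ref_spectra()
  # single reference at unit weight
  um1 <- unmix_spectrum(rs$donor, list(rs$donor))
  expect_equal(um1$coefficients, 1, tolerance = 1e-8)
  expect_lt(um1$residual_norm, 1e-8)

  # orthogonal supports
  g <- seq(400, 700, by = 1)
  A <- spectrum(g, ifelse(g < 520, 1, 0), "emission")
  B <- spectrum(g, ifelse(g >= 540, 1, 0), "emission")
  mixed <- spectrum(g, 0.3 * A$values + 0.7 * B$values, "emission")
  um2 <- unmix_spectrum(mixed, list(A, B))
  expect_equal(um2$coefficients, c(0.3, 0.7), tolerance = 1e-10)

  # overlapping fixture vs an independent bound-constrained solver oracle
  mix_v <- 0.42 * rs$donor$values + 0.13 * rs$acceptor$values
  mixed3 <- spectrum(rs$grid, mix_v, "emission")
  um3 <- unmix_spectrum(mixed3, list(rs$donor, rs$acceptor))
  M <- cbind(rs$donor$values, rs$acceptor$values)
  oracle <- optim(c(0.1, 0.1), function(b) sum((M %*% b - mix_v)^2),
                  method = "L-BFGS-B", lower = c(0, 0),
                  control = list(factr = 1e3))$par
  expect_equal(um3$coefficients, oracle, tolerance = 1e-5)

  # collinear references are flagged but still solved
  expect_warning(um4 <- unmix_spectrum(mixed3, list(rs$donor, rs$donor)),
                 "collinear")
  expect_true(um4$collinear)
})

test_that("apparent FRET efficiency reads back constructed transfer fractions", {
  rs <- make_ref_spectra()
  # pure donor -> 0
  e0 <- apparent_fret_efficiency(rs$donor, rs$acceptor, rs$donor)
  expect_equal(as.numeric(e0), 0, tolerance = 1e-8)
  # pure acceptor, no direct excitation -> 1
  e1 <- apparent_fret_efficiency(rs$donor, rs$acceptor, rs$acceptor)
  expect_equal(as.numeric(e1), 1, tolerance = 1e-8)
  # constructed transfer fraction 0.6
  bd <- barrelfret:::band_area(rs$donor, 450)
  ba <- barrelfret:::band_area(rs$acceptor, 593)
  mixed <- spectrum(rs$grid,
                    0.4 * rs$donor$values + 0.6 * bd / ba * rs$acceptor$values,
                    "emission")
  e6 <- apparent_fret_efficiency(rs$donor, rs$acceptor, mixed)
  expect_equal(as.numeric(e6), 0.6, tolerance = 0.02)
  # invariance under uniform rescaling of all three spectra
  sc <- function(s, c) spectrum(s$wavelengths, c * s$values, s$kind)
  e6b <- apparent_fret_efficiency(sc(rs$donor, 7), sc(rs$acceptor, 7),
                                  sc(mixed, 7))
  expect_equal(as.numeric(e6b), as.numeric(e6), tolerance = 1e-10)
})

test_that("screen ranking is a permutation with correct calls", {
  panels <- simulate_screen_panels(seed = 1)
  res <- screen_panel(panels)
  expect_setequal(res$peptide_id, vapply(panels, `[[`, "", "peptide_id"))
  expect_identical(sum(res$positive), 10L)
  expect_true(all(diff(res$e_app) <= 0))

  # null panels: mixed identical to donor-only -> no positives
  rs <- make_ref_spectra()
  null_panels <- lapply(1:3, function(i) {
    list(peptide_id = paste0("null", i), donor_only = rs$donor,
         acceptor_only = rs$acceptor, mixed = rs$donor)
  })
  expect_identical(sum(screen_panel(null_panels)$positive), 0L)

  # full transfer panel ranks first and is positive
  bd <- barrelfret:::band_area(rs$donor, 450)
  ba <- barrelfret:::band_area(rs$acceptor, 593)
  full <- list(peptide_id = "full", donor_only = rs$donor,
               acceptor_only = rs$acceptor,
               mixed = spectrum(rs$grid, bd / ba * rs$acceptor$values,
                                "emission"))
  res2 <- screen_panel(c(null_panels, list(full)))
  expect_identical(res2$peptide_id[1], "full")
  expect_true(res2$positive[1])

  dup <- c(null_panels, null_panels[1])
  expect_error(screen_panel(dup), "duplicate")
})

test_that("binding fits are unbiased at the reference design", {
  # flat series -> unidentifiable
  flat <- simulate_titration(1e9, noise = noise_spec("gaussian", 0.01, seed = 1))
  ff <- fit_binding(flat)
  expect_false(ff$identifiable)

  # 3 replicates, 2% noise, Kd = 5: mean recovery within 10%, bias < 5%
  kds <- vapply(1:50, function(s) {
    ser <- simulate_titration(5, replicates = 3,
                              noise = noise_spec("gaussian", 0.02,
                                                 seed = 500 + 3 * s))
    fit_binding(ser)$kd
  }, 1)
  expect_lt(abs(mean(kds) - 5) / 5, 0.10)
  expect_lt(abs(median(kds) - 5) / 5, 0.10)
})

test_that("displacement detection distinguishes competitive loss", {
  s1 <- simulate_titration(2, noise = noise_spec("gaussian", 0))
  expect_false(detect_displacement(s1, s1)$displaced)

  # competitor reduces plateau to 10%
  s2 <- s1
  s2$f_norm <- 0.1 * s1$f_norm
  expect_true(detect_displacement(s1, s2)$displaced)

  # mass-action competitive oracle in the site-limited regime: the
  # competitor (Kd 0.05 uM, 30 uM total) outcompetes the dye (Kd 2 uM)
  # for the scarce binding sites on a 0-3 uM peptide grid
  grid <- seq(0, 3, length.out = 12)
  sd_grid <- simulate_titration(2, peptide_grid = grid,
                                noise = noise_spec("gaussian", 0))
  fb <- competitive_bound_oracle(grid, D_tot = 0.5, C_tot = 30,
                                 Kd_d = 2, Kd_c = 0.05)
  s3 <- sd_grid
  s3$f_norm <- 0.05 + 0.95 * fb
  expect_true(detect_displacement(sd_grid, s3)$displaced)

  s4 <- s1[-1, ]
  expect_error(detect_displacement(s1, s4), "match")
})
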