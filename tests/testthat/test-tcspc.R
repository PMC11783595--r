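test_that("analytic convolution reduces to a shifted exponential as sigma -> 0", {
  time <- seq(0, 50, length.out = 2048)
  m <- multiexp_model(1, 4.1, t0_shift = 5)
  plain <- ifelse(time >= 5, exp(-(time - 5) / 4.1), 0)
  conv <- convolve_model(m, time, irf_sigma = 1e-6)
  off_edge <- abs(time - 5) > 1e-3
  expect_lt(max(abs(conv[off_edge] - plain[off_edge])), 1e-8)
})

test_that("analytic convolution matches the FFT oracle", {
  time <- seq(0, 60, length.out = 1500)
  sigma <- fwhm_to_sigma(0.170)
  for (pars in list(list(a = 1, tau = 4.1), list(a = c(0.7, 0.3),
                                                 tau = c(1.2, 12)))) {
    m <- multiexp_model(pars$a, pars$tau, t0_shift = 6)
    conv <- convolve_model(m, time, sigma)
    oracle <- fft_convolve_oracle(pars$a, pars$tau, time, sigma, t0 = 6)
    sel <- conv > 1e-4 * max(conv)
    expect_lt(max(abs(conv[sel] - oracle[sel]) / max(conv)), 1e-6)
  }
})

test_that("a negative-amplitude pair produces a rise then a decay", {
  time <- seq(0, 40, length.out = 2048)
  m <- multiexp_model(c(-1, 1), c(0.98, 4.9), t0_shift = 3)
  conv <- convolve_model(m, time, fwhm_to_sigma(0.170))
  peak_idx <- which.max(conv)
  expect_gt(time[peak_idx], 3)          # rises after t0
  pre <- conv[time > 3.1 & time < time[peak_idx]]
  expect_true(all(diff(pre) > 0))       # monotone rise
  post <- conv[time > time[peak_idx] + 2]
  expect_true(all(diff(post) < 0))      # then decays
})

test_that("reconvolution fitting recovers known models", {
  # noiseless mono-exponential to < 1e-4 relative
  m <- multiexp_model(1, 15.9)
  tr <- simulate_tcspc(m, noise = noise_spec("gaussian", sigma = 0))
  fit <- fit_reconvolution(tr, 1)
  expect_true(fit$converged)
  expect_equal(fit$model$lifetimes, 15.9, tolerance = 1e-4)

  # Poisson trace at the acceptor lifetime within 0.2 ns
  tr2 <- simulate_tcspc(multiexp_model(1, 4.10), t_max = 50,
                        noise = noise_spec("poisson", seed = 5))
  fit2 <- fit_reconvolution(tr2, 1)
  expect_lt(abs(fit2$model$lifetimes - 4.10), 0.2)
  expect_lt(fit2$reduced_chi2, 1.2)

  # two components, ordering preserved
  tr3 <- simulate_tcspc(multiexp_model(c(0.5, 0.5), c(0.98, 15.9)),
                        peak_counts = 5e4,
                        noise = noise_spec("poisson", seed = 9))
  fit3 <- fit_reconvolution(tr3, 2)
  expect_equal(fit3$model$lifetimes[1], 0.98, tolerance = 0.15)
  expect_equal(fit3$model$lifetimes[2], 15.9, tolerance = 0.5)
  expect_true(all(diff(fit3$model$lifetimes) > 0))
})

test_that("weighted least squares cross-checks the Poisson route", {
  tr <- simulate_tcspc(multiexp_model(1, 4.9), t_max = 50,
                       noise = noise_spec("poisson", seed = 2))
  f_mle <- fit_reconvolution(tr, 1, statistic = "poisson_mle")
  f_ls <- fit_reconvolution(tr, 1, statistic = "weighted_ls")
  expect_equal(f_mle$model$lifetimes, f_ls$model$lifetimes, tolerance = 0.02)
})

test_that("average lifetime weights components correctly", {
  m <- multiexp_model(c(1, 1), c(2, 4))
  expect_equal(average_lifetime(m, "intensity"), 20 / 6)
  expect_equal(average_lifetime(m, "amplitude"), 3)
  single <- multiexp_model(2, 7.3)
  expect_equal(average_lifetime(single), 7.3)
  # rise components are excluded; average stays within positive lifetimes
  rised <- multiexp_model(c(-0.5, 1), c(0.5, 4.9))
  expect_equal(average_lifetime(rised), 4.9)
  m2 <- multiexp_model(c(0.2, 0.8), c(1, 10))
  av <- average_lifetime(m2)
  expect_gte(av, 1); expect_lte(av, 10)
})

test_that("BIC model selection identifies the component count", {
  n_ok <- 0
  for (s in 1:10) {
    tr <- simulate_tcspc(multiexp_model(1, 4.1), n_channels = 1024,
                         t_max = 40, peak_counts = 5e3,
                         noise = noise_spec("poisson", seed = 100 + s))
    if (select_model(tr, max_components = 2)$n == 1) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 9)

  # clearly separated bi-exponential (lifetime ratio 10)
  tr2 <- simulate_tcspc(multiexp_model(c(0.5, 0.5), c(1.5, 15)),
                        n_channels = 2048, t_max = 80, peak_counts = 2e4,
                        noise = noise_spec("poisson", seed = 42))
  expect_identical(select_model(tr2, max_components = 3)$n, 2L)
})

test_that("pure background yields a near-zero-amplitude mono fit", {
  counts <- with(list(), {set.seed(1); rpois(1024, 50)})
  time <- (seq_len(1024) - 0.5) * (40 / 1024)
  tr <- decay_trace(time, counts, irf_sigma = fwhm_to_sigma(0.170))
  sel <- select_model(tr, max_components = 2)
  expect_identical(sel$n, 1L)
  f <- sel$fits[[1]]
  # fitted decay contributes a negligible share of the total signal
  decay_part <- sum(f$expected) - length(counts) * f$model$baseline
  expect_lt(abs(decay_part) / sum(counts), 0.05)
})

test_that("acceptor-rise extraction recovers the transfer constant", {
  # heptamer-like rise
  truth <- multiexp_model(c(-0.15, 1), c(0.98, 4.9))
  tr <- simulate_tcspc(truth, t_max = 50,
                       noise = noise_spec("poisson", seed = 21))
  res <- extract_fret_time(tr, acceptor_lifetime_fixed = 4.9)
  expect_true(res$resolvable)
  expect_lt(abs(res$tau_rise - 0.98), 0.2)
  expect_gt(res$rise_ratio, 0.05)

  # octamer-like rise
  truth_o <- multiexp_model(c(-0.15, 1), c(1.3, 5.1))
  tr_o <- simulate_tcspc(truth_o, t_max = 50,
                         noise = noise_spec("poisson", seed = 22))
  res_o <- extract_fret_time(tr_o, acceptor_lifetime_fixed = 5.1)
  expect_lt(abs(res_o$tau_rise - 1.3), 0.2)

  # no rise in truth -> flagged unresolvable (the no-FRET hexamer case)
  flat <- simulate_tcspc(multiexp_model(1, 4.9), t_max = 50,
                         noise = noise_spec("poisson", seed = 23))
  res_f <- extract_fret_time(flat, acceptor_lifetime_fixed = 4.9)
  expect_false(res_f$resolvable)
})

test_that("reported 1-sigma intervals have sane coverage", {
  n_seeds <- 200
  hits <- 0
  for (s in seq_len(n_seeds)) {
    tr <- simulate_tcspc(multiexp_model(1, 4), n_channels = 1024, t_max = 40,
                         peak_counts = 5e3,
                         noise = noise_spec("poisson", seed = 3000 + s))
    f <- fit_reconvolution(tr, 1)
    se <- f$param_errors$lifetimes
    if (is.finite(se) && abs(f$model$lifetimes - 4) <= se) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.60)
  expect_lte(hits / n_seeds, 0.75)
})
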