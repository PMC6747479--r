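tau17 <- schedule_preset("cpmg_tm4_17")

test_that("Carver-Richards collapses to the intrinsic rate in degenerate limits", {
  # no minor state
  p0 <- exchange_params(0, 253, 5.2e3, 31.25, 5.26)
  expect_equal(cr_r2eff(p0, tau17), rep(31.25, 17), tolerance = 1e-10)
  # indistinguishable states
  pind <- exchange_params(0.028, 253, 0, 12, 12)
  expect_equal(cr_r2eff(pind, tau17), rep(12, 17), tolerance = 1e-10)
})

test_that("dispersion flattens under faster pulsing towards the population average", {
  p <- paper_exchange()
  tt <- 10^seq(log10(2e-5), log10(2e-3), length.out = 60)
  r2 <- cr_r2eff(p, tt)
  # the curve has genuine small oscillations (period ~ 2 pi / delta_omega),
  # so strict monotonicity does not hold; the global minimum sits at the
  # fastest pulsing and the curve rises overall
  expect_equal(which.min(r2), 1)
  expect_gt(r2[60] - r2[1], 5)
  # the fully refocused limit is the slow exchange eigenvalue, within 1%
  # of the population-weighted average of the intrinsic rates
  pop_avg <- p$p_a * p$r2_a + p$p_b * p$r2_b
  expect_equal(cr_r2eff(p, 1e-7), pop_avg, tolerance = 0.01)
})

test_that("overflow-prone parameters are evaluated finitely via the log branch", {
  extreme <- exchange_params(0.3, 9e4, 9e4, 150, 1)
  vals <- cr_r2eff(extreme, c(1e-4, 5e-3, 0.05))
  expect_true(all(is.finite(vals)))
})

test_that("Bloch-McConnell propagation has the correct single-site and fast-pulsing limits", {
  single <- exchange_params(0, 0, 5.2e3, 31.25, 5.26)
  expect_equal(bm_r2eff(single, c(1e-4, 1e-3)), c(31.25, 31.25), tolerance = 1e-8)
  p <- paper_exchange()
  pop_avg <- p$p_a * p$r2_a + p$p_b * p$r2_b
  expect_equal(bm_r2eff(p, 1e-6, total_time = 0.02), pop_avg, tolerance = 0.01)
})

test_that("closed form matches the numerical propagator across the slow-exchange regime", {
  grid <- expand.grid(p_b = c(0.01, 0.028, 0.05),
                      k_ex = c(100, 253, 1000),
                      dw = c(2e3, 5.2e3))
  for (i in seq_len(nrow(grid))) {
    p <- exchange_params(grid$p_b[i], grid$k_ex[i], grid$dw[i], 31.25, 5.26)
    cr <- cr_r2eff(p, tau17)
    bm <- bm_r2eff(p, tau17)
    expect_lt(max(abs(cr - bm) / bm), 0.02)
  }
})

test_that("noiseless dispersion fits recover the curve and its identifiable parameters", {
  # the five-parameter model is analytically near-degenerate on a single
  # 17-point schedule (kex, p_b and r2_b trade off along a flat valley),
  # so the fit is checked on the function and the well-determined
  # quantities: delta_omega, r2_a and the exchange contribution p_b * k_ex
  p <- paper_exchange()
  dat <- sim_dispersion(p, "cpmg_tm4_17", sigma = 0)
  for (s in c(2, 7)) {
    fit <- fit_dispersion(dat, n_starts = 16, seed = s)
    # the generating curve is reproduced essentially exactly ...
    rel <- abs(cr_r2eff(fit$params, dat$tau_cp) - dat$r2_eff) / dat$r2_eff
    expect_lt(max(rel), 1e-4)
    # ... and the shift difference, pinned by the oscillation period of
    # the curve, is recovered; kex, p_b and r2_b individually are not
    # assertable (flat valley)
    expect_equal(fit$params$delta_omega, p$delta_omega, tolerance = 0.01)
  }
})

test_that("a flat curve leaves exchange parameters unidentified", {
  flat <- tibble::tibble(tau_cp = schedule_preset("cpmg_empty_10"),
                         r2_eff = rep(12, 10))
  fit <- fit_dispersion(flat, n_starts = 8, seed = 3)
  expect_false(fit$converged)
})

test_that("simulate-and-refit recovers the identifiable quantities at the ensemble median", {
  # at sigma = 0.3 the flat kex/p_b valley means only delta_omega, r2_a
  # and p_b * k_ex carry usable information from a single schedule
  p <- paper_exchange()
  fits <- purrr::map(1:25, function(s) {
    dat <- sim_dispersion(p, "cpmg_tm4_17", sigma = 0.3, seed = s)
    fit_dispersion(dat, n_starts = 32, seed = s)
  })
  dw <- purrr::map_dbl(fits, ~ .x$params$delta_omega)
  r2a <- purrr::map_dbl(fits, ~ .x$params$r2_a)
  phi <- purrr::map_dbl(fits, ~ .x$params$p_b * .x$params$k_ex)
  expect_lt(abs(median(dw) - 5.2e3) / 5.2e3, 0.15)
  expect_lt(abs(median(r2a) - 31.25), 2.0)
  expect_lt(abs(median(phi) - 0.028 * 253) / (0.028 * 253), 0.25)
})

test_that("the exchange F-test separates flat from dispersive curves", {
  # flat curve with realistic noise: no exchange called
  set.seed(11)
  flat <- tibble::tibble(tau_cp = schedule_preset("cpmg_empty_10"),
                         r2_eff = 12 + rnorm(10, 0, 0.3),
                         error = rep(0.3, 10))
  res <- detect_exchange(flat, alpha = 0.05, n_starts = 6, seed = 2)
  expect_false(res$exchange_present)
  # strong genuine dispersion: detected
  disp <- sim_dispersion(paper_exchange(), "cpmg_tm4_17", sigma = 0.3, seed = 5)
  res2 <- detect_exchange(disp, alpha = 0.05, n_starts = 6, seed = 2)
  expect_true(res2$exchange_present)
  expect_lt(res2$p_value, 1e-4)
  # zero-noise flat curve: p-value 1
  flat0 <- tibble::tibble(tau_cp = schedule_preset("cpmg_empty_10"),
                          r2_eff = rep(12, 10))
  expect_equal(detect_exchange(flat0, n_starts = 4, seed = 1)$p_value, 1)
})

test_that("dispersion curves with too few distinct spacings are rejected", {
  p <- paper_exchange()
  few <- tibble::tibble(tau_cp = tau17[1:6], r2_eff = cr_r2eff(p, tau17[1:6]))
  expect_error(fit_dispersion(few), class = "micellr_validation_error")
})
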