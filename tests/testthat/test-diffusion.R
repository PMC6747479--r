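test_that("Stejskal-Tanner forward model matches an independent b-value evaluation", {
  # scalar oracle: b computed by hand from the gradient pulse parameters
  gamma_h <- 2.6752218744e8
  g <- 0.1; delta <- 2e-3; big_delta <- 40e-3; d <- 1e-10
  b_hand <- (g * gamma_h * delta)^2 * (big_delta - delta / 3)
  expect_equal(st_signal(g, 1, d, "1H", delta, big_delta), exp(-b_hand * d),
               tolerance = 1e-12)
  # zero gradient and zero diffusion both leave the amplitude untouched
  expect_equal(st_signal(0, 7, 1e-10, "1H", delta, big_delta), 7)
  expect_equal(st_signal(0.3, 7, 0, "1H", delta, big_delta), 7)
  # strictly decreasing in G for D > 0
  gg <- seq(0, 0.6, length.out = 50)
  expect_true(all(diff(st_signal(gg, 1, 8e-11, "1H", delta, big_delta)) < 0))
  expect_error(st_b_value(0.1, "1H", 0.05, 0.04), class = "micellr_validation_error")
})

test_that("nonlinear ST fit recovers noiseless parameters and agrees with log-linear fit", {
  dat <- noiseless_echo(i0 = 1234, d = 6.5e-11)
  fit <- fit_st(dat, "1H", 4e-3, 40e-3)
  expect_equal(fit$d_tr, 6.5e-11, tolerance = 1e-8)
  expect_equal(fit$i0, 1234, tolerance = 1e-8)
  # linearised regression agrees on noiseless data
  b <- st_b_value(dat$gradient, "1H", 4e-3, 40e-3)
  d_lin <- -unname(coef(lm(log(dat$amplitude) ~ b))[2])
  expect_equal(fit$d_tr, d_lin, tolerance = 1e-6)
  expect_true(all(fit$uncertainties >= 0))
})

test_that("degenerate echo series are rejected", {
  flat <- tibble::tibble(gradient = seq(0.1, 0.5, length.out = 6),
                         amplitude = rep(100, 6))
  expect_error(fit_st(flat, "1H", 4e-3, 40e-3), class = "micellr_fit_failure")
  short <- noiseless_echo()[1:3, ]
  expect_error(fit_st(short, "1H", 4e-3, 40e-3), class = "micellr_validation_error")
})

test_that("median recovered D over noisy replicates is within 1% of truth", {
  d_true <- 8e-11
  ests <- vapply(1:100, function(s) {
    dat <- sim_echo_series(i0 = 100, d = d_true, sigma = 1, seed = s)
    fit_st(dat, "1H", 4e-3, 40e-3)$d_tr
  }, numeric(1))
  expect_lt(abs(median(ests) - d_true) / d_true, 0.01)
})

test_that("polydispersity inversion localises one and two components", {
  dat <- noiseless_echo(i0 = 100, d = 8e-11)
  dist <- invert_polydispersity(dat, "1H", 4e-3, 40e-3, regularization = 1e-6)
  expect_true(all(dist$weight >= 0))
  mode_d <- dist$d[which.max(dist$weight)]
  step <- diff(log10(dist$d))[1]
  expect_lt(abs(log10(mode_d) - log10(8e-11)), 1.5 * step)
  expect_equal(attr(dist, "total_amplitude"), 100, tolerance = 0.01)

  # 50/50 mixture with a decade between components, mild noise; gradient
  # pulses long enough that both components attenuate measurably
  g <- schedule_preset("pgse_1h_25")
  mix <- tibble::tibble(
    gradient = g,
    amplitude = st_signal(g, 50, 5e-11, "1H", 6e-3, 40e-3) +
      st_signal(g, 50, 5e-10, "1H", 6e-3, 40e-3))
  set.seed(42)
  mix$amplitude <- mix$amplitude + rnorm(nrow(mix), 0, 0.5)
  mix$amplitude_error <- 0.5
  dd <- invert_polydispersity(mix, "1H", 6e-3, 40e-3)
  # two local maxima, each within a grid-step-limited margin of a truth
  w <- dd$weight
  peaks <- which(diff(sign(diff(c(-Inf, w, -Inf)))) == -2)
  peaks <- peaks[w[peaks] > 0.05 * max(w)]
  expect_gte(length(peaks), 2)
  top2 <- dd$d[peaks[order(w[peaks], decreasing = TRUE)][1:2]]
  expect_true(any(abs(log10(top2) - log10(5e-11)) < 0.15))
  expect_true(any(abs(log10(top2) - log10(5e-10)) < 0.15))
})

test_that("infinite smoothing flattens the recovered distribution", {
  dat <- noiseless_echo(i0 = 100, d = 8e-11)
  dd <- invert_polydispersity(dat, "1H", 4e-3, 40e-3, grid_size = 32,
                              regularization = 1e9)
  w <- dd$weight / sum(dd$weight)
  expect_lt(max(w) - min(w), 0.05 / 32 * 10)
})

test_that("Stokes-Einstein gives low-30s Angstrom radii for micelle-like diffusion", {
  solv <- solvent_spec(303, viscosity = 0.797e-3)
  res <- stokes_einstein_rh(8.2e-11, solv)
  expect_equal(res$r_h * 1e10, 34, tolerance = 0.02)
  # inverse proportionality and exact round trip
  expect_equal(stokes_einstein_rh(2 * 8.2e-11, solv)$r_h, res$r_h / 2)
  expect_equal(stokes_einstein_d(res$r_h, solv), 8.2e-11, tolerance = 1e-12)
  expect_error(stokes_einstein_rh(-1e-11, solv), class = "micellr_domain_error")
})

test_that("Rh depends on temperature only through T/eta", {
  d <- 8e-11
  s1 <- solvent_spec(293, viscosity = 1.0e-3)
  s2 <- solvent_spec(2 * 293, viscosity = 2 * 1.0e-3) # same T/eta
  expect_equal(stokes_einstein_rh(d, s1)$r_h, stokes_einstein_rh(d, s2)$r_h)
})
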