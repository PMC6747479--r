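n15_r1_times <- schedule_preset("n15_r1")
n15_r2_times <- schedule_preset("n15_r2")
p31_r1_times <- schedule_preset("p31_r1")

test_that("mono-exponential fit recovers noiseless rates exactly", {
  dat <- noiseless_decay(1.59, n15_r1_times)
  fit <- fit_monoexp_decay(dat)
  expect_equal(fit$rate, 1.59, tolerance = 1e-8)
  expect_equal(unname(fit$amplitude_params["i0"]), 100, tolerance = 1e-8)
  expect_true(all(abs(fit$residuals) < 1e-6 * 100))
  expect_false(fit$flagged)
})

test_that("degenerate relaxation series are rejected", {
  expect_error(fit_monoexp_decay(tibble::tibble(time = n15_r1_times,
                                                amplitude = rep(50, 10))),
               class = "micellr_fit_failure")
  rising <- tibble::tibble(time = n15_r1_times,
                           amplitude = 10 * exp(0.5 * n15_r1_times))
  expect_error(fit_monoexp_decay(rising), class = "micellr_fit_failure")
  expect_error(fit_monoexp_decay(noiseless_decay(1, c(0.1, 0.2, 0.3))),
               class = "micellr_insufficient_data")
})

test_that("median recovered R2 under 2% noise is within 2% of truth", {
  r_true <- 28.58
  ests <- vapply(1:200, function(s) {
    dat <- sim_decay("cpmg_decay", r_true, "n15_r2", i0 = 100, sigma = 2, seed = s)
    fit_monoexp_decay(dat)$rate
  }, numeric(1))
  expect_lt(abs(median(ests) - r_true) / r_true, 0.02)
})

test_that("inversion recovery fits the three-parameter model", {
  dat <- tibble::tibble(time = p31_r1_times,
                        amplitude = 1 * (1 - 2 * exp(-0.2 * p31_r1_times)))
  fit <- fit_inversion_recovery(dat)
  expect_equal(fit$rate, 0.2, tolerance = 1e-6)
  expect_equal(unname(fit$amplitude_params["a"]), 2, tolerance = 1e-6)
  # the t = 0 intercept of the model is I0 * (1 - A)
  p <- fit$amplitude_params
  expect_equal(unname(p["i0"] * (1 - p["a"])), -1, tolerance = 1e-6)
})

test_that("median recovered R1 from noisy inversion recovery is within 3%", {
  ests <- vapply(1:200, function(s) {
    dat <- sim_decay("inversion_recovery", 0.2, "p31_r1", i0 = 1, sigma = 0.01,
                     seed = s)
    fit_inversion_recovery(dat)$rate
  }, numeric(1))
  expect_lt(abs(median(ests) - 0.2) / 0.2, 0.03)
})

test_that("reported uncertainty scales linearly with injected noise", {
  med_se <- function(sigma) {
    median(vapply(1:200, function(s) {
      dat <- sim_decay("decay", 1.59, "n15_r1", i0 = 100, sigma = sigma, seed = s)
      fit_monoexp_decay(dat)$uncertainty
    }, numeric(1)))
  }
  se_lo <- med_se(0.5)
  se_hi <- med_se(2.5)
  expect_lt(abs(se_hi / se_lo - 5) / 5, 0.25)
})

test_that("a bi-exponential decay raises the poor-fit flag", {
  tt <- n15_r1_times
  dat <- tibble::tibble(time = tt,
                        amplitude = 60 * exp(-8 * tt) + 40 * exp(-0.3 * tt),
                        error = rep(0.25, length(tt)))
  fit <- fit_monoexp_decay(dat)
  expect_true(fit$flagged)
  # whereas a clean single exponential with the same errors is not flagged
  clean <- tibble::tibble(time = tt, amplitude = 100 * exp(-1.59 * tt),
                          error = rep(0.25, length(tt)))
  expect_false(fit_monoexp_decay(clean)$flagged)
})

test_that("fit_relaxation dispatches on experiment kind", {
  dat <- noiseless_decay(5, n15_r2_times)
  expect_equal(fit_relaxation(dat, "cpmg_decay")$rate, 5, tolerance = 1e-8)
  ir <- tibble::tibble(time = p31_r1_times,
                       amplitude = 1 - 2 * exp(-0.5 * p31_r1_times))
  expect_equal(fit_relaxation(ir, "inversion_recovery")$rate, 0.5,
               tolerance = 1e-6)
})
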