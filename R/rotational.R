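#' Isotropic rigid-rotor spectral density
#'
#' Lorentzian spectral density `J(omega) = (2/5) * tau_c / (1 + omega^2 *
#' tau_c^2)` for overall isotropic tumbling with correlation time
#' `tau_c`.
#'
#' @param omega Angular frequency, rad s^-1.
#' @param tau_c Rotational correlation time, s (> 0).
#' @return Spectral density, s rad^-1.
#' @export
spectral_density <- function(omega, tau_c) {
  stopifnot(tau_c > 0)
  (2 / 5) * tau_c / (1 + (omega * tau_c)^2)
}

#' Amide 15N interaction constants
#'
#' The two constants entering the dipolar + CSA relaxation expressions:
#' the N-H bond length and the 15N chemical-shift anisotropy.
#' Conventional amide values are the defaults.
#'
#' @param r_nh N-H bond length, m. Must lie in (0.9, 1.1) Angstrom.
#' @param delta_sigma 15N CSA, ppm. Must lie in (-200, -100) ppm.
#' @return An object of class `model_free_constants`.
#' @export
model_free_constants <- function(r_nh = 1.02e-10, delta_sigma = -160) {
  if (r_nh <= 0.9e-10 || r_nh >= 1.1e-10) {
    abort("r_nh outside the physically plausible 0.9-1.1 Angstrom window",
          class = "micellr_validation_error")
  }
  if (delta_sigma <= -200 || delta_sigma >= -100) {
    abort("delta_sigma outside the plausible (-200, -100) ppm window",
          class = "micellr_validation_error")
  }
  structure(list(r_nh = r_nh, delta_sigma = delta_sigma),
            class = "model_free_constants")
}

#' Forward 15N R1 and R2 under isotropic rotation
#'
#' Standard amide 15N relaxation rates from N-H dipolar coupling plus 15N
#' CSA, with the isotropic Lorentzian spectral density and no exchange
#' term:
#' \deqn{R_1 = \frac{d^2}{4}[J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H+\omega_N)] + c^2 J(\omega_N)}
#' \deqn{R_2 = \frac{d^2}{8}[4J(0) + J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H) + 6J(\omega_H+\omega_N)] + \frac{c^2}{6}[4J(0) +
#'   3J(\omega_N)]}
#' with `d = mu0 * hbar * gammaH * gammaN / (4 pi r_nh^3)` and
#' `c = delta_sigma * omegaN / sqrt(3)`.
#'
#' @param tau_c Rotational correlation time, s.
#' @param field A [field_spec()].
#' @param constants A [model_free_constants()].
#' @return A tibble with columns `r1`, `r2` (s^-1) and their ratio.
#' @export
forward_r1_r2 <- function(tau_c, field, constants = model_free_constants()) {
  stopifnot(all(tau_c > 0), inherits(field, "field_spec"),
            inherits(constants, "model_free_constants"))
  wh <- 2 * pi * larmor_frequency("1H", field)
  wn <- -2 * pi * larmor_frequency("15N", field) # gamma(15N) < 0; magnitude used
  wn <- abs(wn)
  gh <- abs(nucleus("1H")$gamma)
  gn <- abs(nucleus("15N")$gamma)
  d <- .const$mu0 * .const$hbar * gh * gn / (4 * pi * constants$r_nh^3)
  cc <- abs(constants$delta_sigma) * 1e-6 * wn / sqrt(3)
  r1 <- r2 <- numeric(length(tau_c))
  for (i in seq_along(tau_c)) {
    J <- function(w) spectral_density(w, tau_c[i])
    r1[i] <- (d^2 / 4) * (J(wh - wn) + 3 * J(wn) + 6 * J(wh + wn)) + cc^2 * J(wn)
    r2[i] <- (d^2 / 8) * (4 * J(0) + J(wh - wn) + 3 * J(wn) + 6 * J(wh) +
                            6 * J(wh + wn)) +
      (cc^2 / 6) * (4 * J(0) + 3 * J(wn))
  }
  tibble::tibble(tau_c = tau_c, r1 = r1, r2 = r2, ratio = r2 / r1)
}

.rate_value <- function(x) if (inherits(x, "relax_fit")) x$rate else x
.rate_se <- function(x, default = 0) {
  if (inherits(x, "relax_fit")) x$uncertainty else default
}

#' Rotational correlation time from the R2/R1 ratio (closed form)
#'
#' Inverts the 15N R2/R1 ratio under the isotropic rigid-rotor model with
#' the high-frequency spectral-density terms neglected, which gives the
#' closed form
#' \deqn{\tau_c = \frac{\sqrt{6 R_2/R_1 - 7}}{4 \pi \nu_N}}
#' where `nu_N` is the 15N Larmor frequency. Keeping only `J(0)` and
#' `J(omega_N)` in both rates yields `R2/R1 = 7/6 + (2/3) omega_N^2
#' tau_c^2`, which rearranges to the expression above; it therefore
#' requires `R2/R1 > 7/6`. Uncertainty is first-order propagation from
#' the rate standard errors.
#'
#' @param r1,r2 Relaxation rates (s^-1), as numbers or `relax_fit`
#'   objects (whose uncertainties are then used).
#' @param field A [field_spec()]. There is no default: the field must be
#'   stated explicitly.
#' @param r1_error,r2_error Standard errors used when `r1`/`r2` are
#'   plain numbers.
#' @return An object of class `tauc_result`: list with `tau_c` (s),
#'   `uncertainty` (s) and `method`.
#' @export
#' @examples
#' f <- field_spec(proton_frequency = 599.98e6)
#' tauc_from_ratio(1.59, 10.01, f, r1_error = 0.08, r2_error = 0.81)
tauc_from_ratio <- function(r1, r2, field, r1_error = 0, r2_error = 0) {
  se1 <- .rate_se(r1, r1_error); se2 <- .rate_se(r2, r2_error)
  r1 <- .rate_value(r1); r2 <- .rate_value(r2)
  stopifnot(r1 > 0, r2 > 0, inherits(field, "field_spec"))
  ratio <- r2 / r1
  if (ratio <= 7 / 6) {
    abort("R2/R1 <= 7/6: extreme-narrowing regime, no real correlation time",
          class = "micellr_no_solution_error")
  }
  nu_n <- larmor_frequency("15N", field)
  tau_c <- sqrt(6 * ratio - 7) / (4 * pi * nu_n)
  se_ratio <- ratio * sqrt((se1 / r1)^2 + (se2 / r2)^2)
  se_tau <- 3 * se_ratio / (4 * pi * nu_n * sqrt(6 * ratio - 7))
  structure(list(tau_c = tau_c, uncertainty = se_tau, method = "ratio_approximation"),
            class = "tauc_result")
}

#' Rotational correlation time by exact inversion of the forward model
#'
#' Numerically inverts the full dipolar + CSA `R2/R1` ratio of
#' [forward_r1_r2()] by bracketed root finding on `tau_c` in
#' `[0.1, 100]` ns. Cross-validates the closed-form
#' [tauc_from_ratio()] estimator.
#'
#' @inheritParams tauc_from_ratio
#' @param constants A [model_free_constants()].
#' @return An object of class `tauc_result` with `method =
#'   "exact_inversion"`.
#' @export
tauc_exact <- function(r1, r2, field, constants = model_free_constants(),
                       r1_error = 0, r2_error = 0) {
  se1 <- .rate_se(r1, r1_error); se2 <- .rate_se(r2, r2_error)
  r1 <- .rate_value(r1); r2 <- .rate_value(r2)
  stopifnot(r1 > 0, r2 > 0, inherits(field, "field_spec"))
  target <- r2 / r1
  f <- function(tc) forward_r1_r2(tc, field, constants)$ratio - target
  lo <- 0.1e-9; hi <- 100e-9
  if (f(lo) * f(hi) > 0) {
    abort("R2/R1 ratio outside the invertible range for tau_c in [0.1, 100] ns",
          class = "micellr_inversion_failure")
  }
  root <- uniroot(f, c(lo, hi), tol = 1e-15)$root
  # propagate via the local slope of ratio(tau_c)
  eps <- root * 1e-4
  slope <- (forward_r1_r2(root + eps, field, constants)$ratio -
              forward_r1_r2(root - eps, field, constants)$ratio) / (2 * eps)
  se_ratio <- target * sqrt((se1 / r1)^2 + (se2 / r2)^2)
  structure(list(tau_c = root, uncertainty = abs(se_ratio / slope),
                 method = "exact_inversion"),
            class = "tauc_result")
}

#' @export
print.tauc_result <- function(x, ...) {
  cat(sprintf("tau_c = %.3g +/- %.2g ns (%s)\n",
              x$tau_c * 1e9, x$uncertainty * 1e9, x$method))
  invisible(x)
}
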