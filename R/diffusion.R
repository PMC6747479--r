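#' Stejskal-Tanner echo attenuation
#'
#' Forward model for pulsed-field-gradient spin-echo (PGSE) attenuation,
#' `I = I0 * exp(-D * (G * gamma * delta)^2 * (Delta - delta/3))`, where
#' `G` is the gradient strength, `gamma` the gyromagnetic ratio of the
#' observed nucleus, `delta` the gradient pulse duration and `Delta` the
#' diffusion time.
#'
#' @param g Gradient strength(s), T/m.
#' @param i0 Zero-gradient amplitude.
#' @param d Translational diffusion coefficient, m^2 s^-1.
#' @param nuc Nucleus name or registry row (sets gamma).
#' @param delta Gradient pulse duration, s.
#' @param big_delta Diffusion time, s. Must exceed `delta`.
#' @return Amplitude(s), same length as `g`.
#' @export
#' @examples
#' st_signal(seq(0, 0.5, 0.1), i0 = 1, d = 8e-11, nuc = "1H",
#'           delta = 2e-3, big_delta = 40e-3)
st_signal <- function(g, i0, d, nuc, delta, big_delta) {
  i0 * exp(-d * st_b_value(g, nuc, delta, big_delta))
}

#' Stejskal-Tanner b-values
#'
#' `b = (G * gamma * delta)^2 * (Delta - delta/3)` in s m^-2.
#'
#' @inheritParams st_signal
#' @return b-value(s), s m^-2.
#' @export
st_b_value <- function(g, nuc, delta, big_delta) {
  if (is.character(nuc)) nuc <- nucleus(nuc)
  stopifnot(delta > 0, big_delta > 0)
  if (delta >= big_delta) {
    abort("gradient duration delta must be shorter than diffusion time Delta",
          class = "micellr_validation_error")
  }
  (g * abs(nuc$gamma) * delta)^2 * (big_delta - delta / 3)
}

.check_echo_series <- function(data) {
  stopifnot(is.data.frame(data), all(c("gradient", "amplitude") %in% names(data)))
  if (nrow(data) < 4) {
    abort("echo series needs at least 4 points", class = "micellr_validation_error")
  }
  if (any(data$gradient < 0) || is.unsorted(data$gradient, strictly = TRUE)) {
    abort("gradient strengths must be non-negative and strictly increasing",
          class = "micellr_validation_error")
  }
  invisible(data)
}

#' Fit the Stejskal-Tanner equation to a PGSE series
#'
#' Nonlinear least squares of `(I0, D)` on a tibble with columns
#' `gradient` (T/m) and `amplitude`, plus optional `amplitude_error` used
#' as inverse-variance weights. Fitting is done in amplitude space;
#' starting values come from a log-linear regression of amplitude on
#' b-value.
#'
#' @param data Data frame with columns `gradient`, `amplitude`, optional
#'   `amplitude_error`.
#' @inheritParams st_signal
#' @return An object of class `st_fit` with elements `d_tr`, `i0`,
#'   `uncertainties` (named standard errors), `covariance`, `residuals`,
#'   `data` and the pulse geometry. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
fit_st <- function(data, nuc, delta, big_delta) {
  .check_echo_series(data)
  if (any(data$amplitude <= 0)) {
    abort("echo amplitudes must be positive", class = "micellr_validation_error")
  }
  if (is.character(nuc)) nuc <- nucleus(nuc)
  b <- st_b_value(data$gradient, nuc, delta, big_delta)
  y <- data$amplitude
  w <- if ("amplitude_error" %in% names(data)) 1 / data$amplitude_error^2 else rep(1, length(y))

  # log-linear initial values; slope >= 0 means the series does not decay
  init <- stats::lm(log(y) ~ b)
  d0 <- -unname(coef(init)[2])
  if (!is.finite(d0) || d0 <= 0) {
    abort("series does not decay with gradient strength: cannot fit a positive D",
          class = "micellr_fit_failure")
  }
  i00 <- exp(unname(coef(init)[1]))

  fit <- minpack.lm::nls.lm(
    par = c(log_i0 = log(i00), log_d = log(d0)),
    fn = function(p) sqrt(w) * (y - exp(p[["log_i0"]]) * exp(-exp(p[["log_d"]]) * b)),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- fit$par
  i0_hat <- exp(p[["log_i0"]])
  d_hat <- exp(p[["log_d"]])
  # delta-method covariance on the natural scale
  dof <- length(y) - 2
  s2 <- fit$deviance / dof
  cov_log <- tryCatch(s2 * solve(fit$hessian / 2), error = function(e) matrix(NA_real_, 2, 2))
  jac_nat <- diag(c(i0_hat, d_hat))
  cov_nat <- jac_nat %*% cov_log %*% t(jac_nat)
  dimnames(cov_nat) <- list(c("i0", "d_tr"), c("i0", "d_tr"))

  structure(list(
    d_tr = d_hat, i0 = i0_hat,
    uncertainties = c(i0 = sqrt(cov_nat[1, 1]), d_tr = sqrt(cov_nat[2, 2])),
    covariance = cov_nat,
    residuals = y - st_signal(data$gradient, i0_hat, d_hat, nuc, delta, big_delta),
    data = tibble::as_tibble(data),
    nucleus = nuc$name, delta = delta, big_delta = big_delta
  ), class = "st_fit")
}

#' @export
print.st_fit <- function(x, ...) {
  cat("Stejskal-Tanner fit (", x$nucleus, ")\n", sep = "")
  cat(sprintf("  D_tr = %.4g +/- %.2g m^2/s\n", x$d_tr, x$uncertainties[["d_tr"]]))
  cat(sprintf("  I0   = %.4g +/- %.2g\n", x$i0, x$uncertainties[["i0"]]))
  invisible(x)
}

#' Regularised inversion of a PGSE series onto a diffusion grid
#'
#' Inverse-Laplace style analysis of echo attenuation to expose
#' polydispersity: non-negative least squares of the amplitudes onto a
#' log-spaced grid of diffusion coefficients with first-difference
#' Tikhonov smoothing. When `regularization` is `NULL` it is chosen by
#' the discrepancy principle against the noise level estimated from a
#' single-component fit (or taken from `amplitude_error`).
#'
#' @inheritParams fit_st
#' @param grid_size Number of grid points (default 64).
#' @param decades Width of the grid in decades, centred on the
#'   single-component estimate (default 4).
#' @param regularization Smoothing parameter lambda; `NULL` for automatic
#'   selection.
#' @return An object of class `diffusion_dist`: tibble of `d` (m^2/s) and
#'   `weight`, with the chosen `regularization`, the reconstruction
#'   residual and the total fitted amplitude as attributes.
#' @export
invert_polydispersity <- function(data, nuc, delta, big_delta,
                                  grid_size = 64, decades = 4,
                                  regularization = NULL) {
  .check_echo_series(data)
  if (is.character(nuc)) nuc <- nucleus(nuc)
  mono <- fit_st(data, nuc, delta, big_delta)
  grid <- 10^seq(log10(mono$d_tr) - decades / 2, log10(mono$d_tr) + decades / 2,
                 length.out = grid_size)
  b <- st_b_value(data$gradient, nuc, delta, big_delta)
  A <- exp(-outer(b, grid))
  if (qr(A)$rank < 2 || nrow(A) < 4) {
    abort("design matrix is singular: too few points for the grid",
          class = "micellr_ill_posed_error")
  }
  y <- data$amplitude
  # first-difference penalty: in the lambda -> Inf limit the weights flatten
  L <- matrix(0, grid_size - 1, grid_size)
  for (i in seq_len(grid_size - 1)) L[i, i:(i + 1)] <- c(1, -1)

  solve_w <- function(lambda) {
    if (lambda >= 1e4 * max(abs(A))) {
      # analytic lambda -> Inf limit of the first-difference penalty:
      # the weights are forced constant, fitted by least squares
      a1 <- rowSums(A)
      return(rep(max(sum(a1 * y) / sum(a1^2), 0), grid_size))
    }
    # tiny ridge keeps the augmented system full rank
    ridge <- 1e-8 * max(abs(A)) * diag(grid_size)
    Aaug <- rbind(A, lambda * L, ridge)
    yaug <- c(y, rep(0, nrow(L) + grid_size))
    pracma::lsqnonneg(Aaug, yaug)$x
  }
  noise <- if ("amplitude_error" %in% names(data)) {
    sqrt(mean(data$amplitude_error^2))
  } else {
    sd(mono$residuals)
  }
  if (is.null(regularization)) {
    # discrepancy principle: largest lambda whose reconstruction residual
    # stays at the noise floor
    lambdas <- 10^seq(-4, 2, length.out = 25) * max(y)
    target <- max(noise, 1e-12 * max(y)) * sqrt(length(y))
    pick <- lambdas[1]
    for (lam in lambdas) {
      wsol <- solve_w(lam)
      if (sqrt(sum((A %*% wsol - y)^2)) <= target) pick <- lam else break
    }
    regularization <- pick
  }
  wsol <- solve_w(regularization)
  res <- as.numeric(A %*% wsol - y)
  out <- tibble::tibble(d = grid, weight = wsol)
  structure(out,
            class = c("diffusion_dist", class(out)),
            regularization = regularization,
            residual = sqrt(mean(res^2)),
            total_amplitude = sum(wsol),
            mono_i0 = mono$i0)
}

#' Hydrodynamic radius from the Stokes-Einstein relation
#'
#' `Rh = kB * T / (6 * pi * eta * D)` for a sphere diffusing at the
#' measured rate.
#'
#' @param d_tr Translational diffusion coefficient, m^2 s^-1 (> 0).
#' @param solvent A [solvent_spec()].
#' @return An object of class `hydrodynamic_result`: list with `r_h` (m),
#'   `d_tr` and the solvent.
#' @export
#' @examples
#' stokes_einstein_rh(8.2e-11, solvent_spec(303)) # ~34 Angstrom micelle
stokes_einstein_rh <- function(d_tr, solvent) {
  stopifnot(inherits(solvent, "solvent_spec"))
  if (d_tr <= 0) {
    abort("diffusion coefficient must be positive", class = "micellr_domain_error")
  }
  r_h <- .const$kb * solvent$temperature / (6 * pi * solvent$viscosity * d_tr)
  structure(list(r_h = r_h, d_tr = d_tr, solvent = solvent),
            class = "hydrodynamic_result")
}

#' @rdname stokes_einstein_rh
#' @param r_h Hydrodynamic radius, m (> 0).
#' @return `stokes_einstein_d()` returns the diffusion coefficient in
#'   m^2 s^-1.
#' @export
stokes_einstein_d <- function(r_h, solvent) {
  stopifnot(inherits(solvent, "solvent_spec"))
  if (r_h <= 0) abort("radius must be positive", class = "micellr_domain_error")
  .const$kb * solvent$temperature / (6 * pi * solvent$viscosity * r_h)
}

#' @export
print.hydrodynamic_result <- function(x, ...) {
  cat(sprintf("Hydrodynamic radius: %.1f Angstrom (D = %.3g m^2/s, T = %.1f K, eta = %.3g Pa s)\n",
              x$r_h * 1e10, x$d_tr, x$solvent$temperature, x$solvent$viscosity))
  invisible(x)
}
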