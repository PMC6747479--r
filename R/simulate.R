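# Acquisition schedules shipped as named presets. Relaxation evolution
# times and CPMG pulse spacings are in seconds; PGSE gradients in T/m.
.presets <- list(
  # 15N longitudinal relaxation: ten evolution times
  n15_r1 = c(10, 90, 170, 290, 410, 550, 690, 850, 1010, 1250) / 1000,
  # 15N transverse (CPMG train) relaxation: eight evolution times
  n15_r2 = c(10, 30, 50, 70, 90, 130, 170, 210) / 1000,
  # 31P inversion recovery: ten delays
  p31_r1 = c(0.0625, 0.125, 0.25, 0.5, 1, 2, 4, 8, 16, 32),
  # 31P transverse relaxation: nine delays
  p31_r2 = c(1.25, 2.5, 5, 10, 20, 40, 80, 160, 320) / 1000,
  # 31P CPMG dispersion with the peptide loaded: 17 pulse spacings,
  # duplicates kept as independent observations
  cpmg_tm4_17 = c(50, 60, 70, 80, 100, 200, 200, 500, 900, 900,
                  1100, 1100, 1200, 1300, 1400, 1500, 2000) * 1e-6,
  # 31P CPMG dispersion of the empty micelle: 10 pulse spacings
  cpmg_empty_10 = c(50, 80, 100, 300, 500, 900, 1000, 1400, 1500, 2000) * 1e-6,
  # 1H PGSE: 25 gradient steps up to the 60 G/cm probe maximum
  pgse_1h_25 = seq(0.02, 0.60, length.out = 25)
)

#' Named acquisition-schedule presets
#'
#' Returns one of the schedules the generators and readers share:
#' `n15_r1`, `n15_r2`, `p31_r1`, `p31_r2` (relaxation evolution times,
#' s), `cpmg_tm4_17`, `cpmg_empty_10` (CPMG pulse spacings, s) or
#' `pgse_1h_25` (gradient strengths, T/m).
#'
#' @param name Preset name; call with no arguments to list all presets.
#' @return Numeric vector, or a character vector of names.
#' @export
schedule_preset <- function(name = NULL) {
  if (is.null(name)) return(names(.presets))
  if (!name %in% names(.presets)) {
    abort(paste0("unknown preset '", name, "'; available: ",
                 paste(names(.presets), collapse = ", ")),
          class = "micellr_preset_error")
  }
  .presets[[name]]
}

# Deterministic sub-stream seed from (generator name, user seed) so the
# three generators draw independent noise for the same seed.
.stream_seed <- function(name, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

.with_stream <- function(name, seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(.stream_seed(name, seed))
  force(code)
}

.sim_attrs <- function(tbl, truth, sigma, seed) {
  attr(tbl, "truth") <- truth
  attr(tbl, "sigma") <- sigma
  attr(tbl, "seed") <- seed
  tbl
}

#' Ground truth embedded in a simulated series
#'
#' @param x A tibble produced by [sim_echo_series()], [sim_decay()] or
#'   [sim_dispersion()].
#' @return Named list of the generating parameters, with `sigma` and
#'   `seed` attached.
#' @export
sim_truth <- function(x) {
  truth <- attr(x, "truth")
  if (is.null(truth)) {
    abort("object carries no simulation provenance", class = "micellr_validation_error")
  }
  c(truth, list(sigma = attr(x, "sigma"), seed = attr(x, "seed")))
}

#' Simulate a PGSE echo-attenuation series
#'
#' Forward Stejskal-Tanner curve plus additive Gaussian noise. The
#' generating parameters are embedded as provenance for blind recovery
#' tests.
#'
#' @param i0 Zero-gradient amplitude.
#' @param d Diffusion coefficient, m^2 s^-1.
#' @param nuc Nucleus name (sets gamma).
#' @param delta Gradient pulse duration, s.
#' @param big_delta Diffusion time, s; the conventional defaults per
#'   nucleus are 40 ms (1H), 60 ms (31P) and 200 ms (2H), but the value
#'   is always explicit here.
#' @param gradients Gradient strengths (T/m), default the 25-step preset.
#' @param sigma Gaussian noise standard deviation (amplitude units).
#' @param seed Integer seed; identical seeds give identical series.
#' @return Tibble with `gradient`, `amplitude` and an `amplitude_error`
#'   column equal to `sigma` when `sigma > 0`; provenance retrievable via
#'   [sim_truth()].
#' @export
sim_echo_series <- function(i0, d, nuc = "1H", delta = 4e-3, big_delta = 40e-3,
                            gradients = schedule_preset("pgse_1h_25"),
                            sigma = 0, seed = 1) {
  if (sigma < 0) abort("sigma must be non-negative", class = "micellr_validation_error")
  mu <- st_signal(gradients, i0, d, nuc, delta, big_delta)
  noise <- if (sigma > 0) .with_stream("echo", seed, rnorm(length(mu), 0, sigma)) else rep(0, length(mu))
  out <- tibble::tibble(gradient = gradients, amplitude = mu + noise)
  if (sigma > 0) out$amplitude_error <- rep(sigma, nrow(out))
  .sim_attrs(out, list(i0 = i0, d = d, nucleus = nuc, delta = delta,
                       big_delta = big_delta), sigma, seed)
}

#' Simulate a relaxation decay or inversion-recovery series
#'
#' @param kind `"decay"`, `"cpmg_decay"` or `"inversion_recovery"`.
#' @param rate Relaxation rate, s^-1.
#' @param schedule A preset name (see [schedule_preset()]) or a numeric
#'   vector of evolution times in seconds.
#' @param i0 Equilibrium amplitude.
#' @param a Inversion factor (inversion recovery only; 2 = ideal).
#' @param sigma,seed As in [sim_echo_series()].
#' @return Tibble with `time`, `amplitude`, optional `error`.
#' @export
sim_decay <- function(kind = c("decay", "cpmg_decay", "inversion_recovery"),
                      rate, schedule, i0 = 100, a = 2, sigma = 0, seed = 1) {
  kind <- match.arg(kind)
  if (sigma < 0) abort("sigma must be non-negative", class = "micellr_validation_error")
  times <- if (is.character(schedule)) schedule_preset(schedule) else schedule
  mu <- if (kind == "inversion_recovery") {
    i0 * (1 - a * exp(-rate * times))
  } else {
    i0 * exp(-rate * times)
  }
  noise <- if (sigma > 0) .with_stream("decay", seed, rnorm(length(mu), 0, sigma)) else rep(0, length(mu))
  out <- tibble::tibble(time = times, amplitude = mu + noise)
  if (sigma > 0) out$error <- rep(sigma, nrow(out))
  truth <- list(kind = kind, rate = rate, i0 = i0)
  if (kind == "inversion_recovery") truth$a <- a
  .sim_attrs(out, truth, sigma, seed)
}

#' Simulate a CPMG relaxation-dispersion curve
#'
#' Forward two-site exchange dispersion from either the Carver-Richards
#' closed form or the Bloch-McConnell propagator, plus Gaussian noise.
#' Duplicate pulse spacings in the schedule are emitted as independent
#' rows.
#'
#' @param params An [exchange_params()].
#' @param schedule Preset name (default the 17-spacing loaded-micelle
#'   schedule) or numeric pulse spacings in seconds.
#' @param sigma,seed As in [sim_echo_series()].
#' @param generator `"cr"` (closed form) or `"bm"` (numerical
#'   propagation).
#' @param total_time Passed to [bm_r2eff()] when `generator = "bm"`.
#' @return Tibble with `tau_cp`, `r2_eff`, optional `error`.
#' @export
sim_dispersion <- function(params, schedule = "cpmg_tm4_17", sigma = 0,
                           seed = 1, generator = c("cr", "bm"),
                           total_time = 0.2) {
  generator <- match.arg(generator)
  if (sigma < 0) abort("sigma must be non-negative", class = "micellr_validation_error")
  tau <- if (is.character(schedule)) schedule_preset(schedule) else schedule
  mu <- if (generator == "cr") cr_r2eff(params, tau) else bm_r2eff(params, tau, total_time)
  noise <- if (sigma > 0) .with_stream("dispersion", seed, rnorm(length(mu), 0, sigma)) else rep(0, length(mu))
  out <- tibble::tibble(tau_cp = tau, r2_eff = mu + noise)
  if (sigma > 0) out$error <- rep(sigma, nrow(out))
  .sim_attrs(out, list(params = params, generator = generator), sigma, seed)
}
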