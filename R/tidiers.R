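#' Tidy a Stejskal-Tanner fit
#'
#' @param x An `st_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @method tidy st_fit
#' @export
tidy.st_fit <- function(x, ...) {
  tibble::tibble(term = c("i0", "d_tr"),
                 estimate = c(x$i0, x$d_tr),
                 std.error = unname(x$uncertainties[c("i0", "d_tr")]))
}

#' @rdname tidy.st_fit
#' @method glance st_fit
#' @export
glance.st_fit <- function(x, ...) {
  tibble::tibble(d_tr = x$d_tr, i0 = x$i0,
                 sigma = sd(x$residuals), nobs = nrow(x$data))
}

#' Tidy a relaxation fit
#'
#' @param x A `relax_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @method tidy relax_fit
#' @export
tidy.relax_fit <- function(x, ...) {
  terms <- c(names(x$amplitude_params), "rate")
  est <- c(unname(x$amplitude_params), x$rate)
  ses <- sqrt(diag(x$covariance))
  tibble::tibble(term = terms, estimate = est,
                 std.error = unname(ses[terms]))
}

#' @rdname tidy.relax_fit
#' @method glance relax_fit
#' @export
glance.relax_fit <- function(x, ...) {
  tibble::tibble(rate = x$rate, std.error = x$uncertainty, kind = x$kind,
                 flagged = x$flagged, sigma = sd(x$residuals),
                 nobs = nrow(x$data))
}

#' Tidy a Carver-Richards dispersion fit
#'
#' @param x A `dispersion_fit`.
#' @param ... Unused.
#' @return One row per exchange parameter: `term`, `estimate`,
#'   `std.error`.
#' @method tidy dispersion_fit
#' @export
tidy.dispersion_fit <- function(x, ...) {
  terms <- c("p_b", "k_ex", "delta_omega", "r2_a", "r2_b")
  tibble::tibble(term = terms,
                 estimate = unlist(x$params[terms], use.names = FALSE),
                 std.error = unname(x$uncertainties[terms]))
}

#' @rdname tidy.dispersion_fit
#' @method glance dispersion_fit
#' @export
glance.dispersion_fit <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, converged = x$converged,
                 at_bound = x$at_bound, n_starts = x$n_starts,
                 nobs = nrow(x$data))
}
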