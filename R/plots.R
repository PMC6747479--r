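#' Plot a PGSE fit
#'
#' Echo amplitudes against gradient strength with the fitted
#' Stejskal-Tanner curve, log-scaled amplitude axis.
#'
#' @param object An `st_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot st_fit
#' @export
autoplot.st_fit <- function(object, ...) {
  grid <- tibble::tibble(gradient = seq(min(object$data$gradient),
                                        max(object$data$gradient),
                                        length.out = 200))
  grid$amplitude <- st_signal(grid$gradient, object$i0, object$d_tr,
                              object$nucleus, object$delta, object$big_delta)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$gradient, y = .data$amplitude)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "gradient strength (T/m)", y = "echo amplitude",
                  title = sprintf("D = %.3g m\u00b2/s", object$d_tr))
}

#' Plot a relaxation fit
#'
#' @param object A `relax_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot relax_fit
#' @export
autoplot.relax_fit <- function(object, ...) {
  tgrid <- seq(min(object$data$time), max(object$data$time), length.out = 200)
  p <- object$amplitude_params
  yhat <- if (object$kind == "inversion_recovery") {
    p[["i0"]] * (1 - p[["a"]] * exp(-object$rate * tgrid))
  } else {
    p[["i0"]] * exp(-object$rate * tgrid)
  }
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = tibble::tibble(time = tgrid, amplitude = yhat),
                       colour = "steelblue") +
    ggplot2::labs(x = "evolution time (s)", y = "peak amplitude",
                  title = sprintf("R = %.3g \u00b1 %.2g s\u207b\u00b9",
                                  object$rate, object$uncertainty))
}

#' Plot a relaxation-dispersion fit
#'
#' Effective R2 against CPMG pulse spacing with the fitted
#' Carver-Richards curve.
#'
#' @param object A `dispersion_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dispersion_fit
#' @export
autoplot.dispersion_fit <- function(object, ...) {
  tgrid <- exp(seq(log(min(object$data$tau_cp)), log(max(object$data$tau_cp)),
                   length.out = 200))
  curve <- tibble::tibble(tau_cp = tgrid, r2_eff = cr_r2eff(object$params, tgrid))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$tau_cp * 1e3, y = .data$r2_eff)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::labs(x = expression(tau[cp] ~ "(ms)"),
                  y = expression(R[2 * ",eff"] ~ (s^-1)))
}

#' Plot a helical wheel
#'
#' Residues on the helical wheel, coloured by face.
#'
#' @param object A `helical_wheel`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot helical_wheel
#' @export
autoplot.helical_wheel <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$x <- cos(df$angle * pi / 180)
  df$y <- sin(df$angle * pi / 180)
  df$label <- paste0(df$residue_type, df$residue_number)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$face)) +
    ggplot2::geom_point(size = 4) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       nudge_x = 0.12 * sign(df$x + 1e-9), size = 3,
                       show.legend = FALSE) +
    ggplot2::coord_fixed(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL)
}

#' Chemical-shift perturbation bar plot
#'
#' Signed per-residue shift differences as a bar chart.
#'
#' @param csp_tbl Output of [csp()].
#' @return A ggplot.
#' @export
plot_csp <- function(csp_tbl) {
  stopifnot(all(c("residue_number", "delta") %in% names(csp_tbl)))
  df <- csp_tbl[!csp_tbl$missing, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue_number, y = .data$delta)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "residue", y = expression(Delta * delta ~ "(ppm)"))
}
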