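# Diagnostic ggplot2 methods for the package's result types.

#' Plot a CSP profile as a per-residue bar chart
#'
#' @param object A `csp_profile` tibble.
#' @param threshold_ppm Optional horizontal threshold line (default 0.025).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot csp_profile
#' @export
autoplot.csp_profile <- function(object, threshold_ppm = 0.025, ...) {
  dat <- object[object$matched, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$residue_number, y = .data$csp_avg)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_hline(yintercept = threshold_ppm, linetype = "dashed") +
    ggplot2::labs(x = "Residue", y = "Combined CSP (ppm)") +
    ggplot2::theme_minimal()
}

#' Plot observed vs fitted binding curves of a titration fit
#'
#' Shows the shared fraction-bound curve against ligand concentration,
#' with per-point values marked.
#'
#' @param object A `binding_curve_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot binding_curve_fit
#' @export
autoplot.binding_curve_fit <- function(object, ...) {
  fb <- object$fraction_bound
  grid <- tibble(
    L_total_uM = seq(0, max(fb$L_total_uM), length.out = 100)
  )
  grid$fraction_bound <- fraction_bound(object$P_total_uM, grid$L_total_uM,
                                        object$Kd_uM)
  ggplot2::ggplot(fb, ggplot2::aes(x = .data$L_total_uM, y = .data$fraction_bound)) +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Total ligand (uM)", y = "Fraction bound",
      title = sprintf("Kd = %.1f uM (%s fit)", object$Kd_uM, object$mode)
    ) +
    ggplot2::theme_minimal()
}

#' Plot observed vs back-calculated RDCs
#'
#' The standard correlation plot: perfect agreement lies on the diagonal.
#'
#' @param object An `rdc_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rdc_fit
#' @export
autoplot.rdc_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$D_obs_Hz, y = .data$D_calc_Hz)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Observed 1D(NH) (Hz)", y = "Back-calculated 1D(NH) (Hz)",
      title = sprintf("R-factor = %.1f%%, Da = %.2f Hz, R = %.2f",
                      object$r_factor, object$tensor$Da,
                      object$tensor$rhombicity)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ITC isotherm and (optionally) a model fit
#'
#' @param object An `itc_isotherm` or `itc_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot itc_isotherm
#' @export
autoplot.itc_isotherm <- function(object, ...) {
  dat <- object[object$use_flag == 1L, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$molar_ratio, y = .data$heat_ucal)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Molar ratio (titrant/titrand)",
                  y = "Heat per injection (ucal)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.itc_isotherm
#' @method autoplot itc_fit
#' @export
autoplot.itc_fit <- function(object, ...) {
  dat <- object$residuals[object$residuals$used, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$molar_ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$heat_ucal)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_ucal)) +
    ggplot2::labs(
      x = "Molar ratio (titrant/titrand)", y = "Heat per injection (ucal)",
      title = sprintf("%s fit, residual norm %.3g ucal",
                      object$model, object$residual_norm)
    ) +
    ggplot2::theme_minimal()
}
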