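# broom-style tidiers for the fitted-object classes.

#' Tidy a titration binding fit
#'
#' @param x A `binding_curve_fit`.
#' @param ... Unused.
#' @return One row per parameter (`term`, `estimate`, `std.error`); in
#'   per-residue mode, one `Kd` row per residue.
#' @method tidy binding_curve_fit
#' @export
tidy.binding_curve_fit <- function(x, ...) {
  if (x$mode == "per_residue" && !is.null(x$per_residue)) {
    return(tibble(
      term = sprintf("Kd_uM[res %d]", x$per_residue$residue_number),
      estimate = x$per_residue$Kd_uM,
      std.error = x$per_residue$Kd_se_uM
    ))
  }
  tibble(term = "Kd_uM", estimate = x$Kd_uM, std.error = x$Kd_se_uM)
}

#' @rdname tidy.binding_curve_fit
#' @method glance binding_curve_fit
#' @export
glance.binding_curve_fit <- function(x, ...) {
  tibble(Kd_uM = x$Kd_uM, Kd_se_uM = x$Kd_se_uM, mode = x$mode,
         residual_norm = x$residual_norm,
         n_points = x$n_points, n_residues = x$n_residues)
}

#' Tidy an RDC tensor fit
#'
#' @param x An `rdc_fit`.
#' @param ... Unused.
#' @return One row per tensor parameter (Da, rhombicity, Euler angles).
#' @method tidy rdc_fit
#' @export
tidy.rdc_fit <- function(x, ...) {
  tibble(
    term = c("Da_Hz", "rhombicity", "euler_phi_deg", "euler_theta_deg",
             "euler_psi_deg"),
    estimate = c(x$tensor$Da, x$tensor$rhombicity, x$tensor$euler_deg)
  )
}

#' @rdname tidy.rdc_fit
#' @method glance rdc_fit
#' @export
glance.rdc_fit <- function(x, ...) {
  tibble(Da_Hz = x$tensor$Da, rhombicity = x$tensor$rhombicity,
         r_factor = x$r_factor, rmsd_Hz = x$rmsd, n_rdcs = x$n_rdcs,
         condition_number = x$condition_number)
}

#' Per-residue observed vs calculated couplings of an RDC fit
#'
#' @param x An `rdc_fit`.
#' @param ... Unused.
#' @return The fit's per-residue data tibble.
#' @method augment rdc_fit
#' @export
augment.rdc_fit <- function(x, ...) x$data

#' Tidy an ITC isotherm fit
#'
#' @param x An `itc_fit`.
#' @param ... Unused.
#' @return One row per fitted parameter (`term`, `estimate`, `std.error`).
#' @method tidy itc_fit
#' @export
tidy.itc_fit <- function(x, ...) {
  tibble(term = x$params$term, estimate = x$params$estimate,
         std.error = x$params$se)
}

#' @rdname tidy.itc_fit
#' @method glance itc_fit
#' @export
glance.itc_fit <- function(x, ...) {
  tibble(model = x$model, residual_norm = x$residual_norm,
         n_used = x$n_used, c_value = x$c_value, converged = x$converged)
}

#' Per-injection fitted heats and residuals of an ITC fit
#'
#' @param x An `itc_fit`.
#' @param ... Unused.
#' @return The fit's per-injection residual tibble.
#' @method augment itc_fit
#' @export
augment.itc_fit <- function(x, ...) x$residuals

#' Tidy a per-domain vs joint RDC comparison
#'
#' @param x An `rdc_domain_comparison`.
#' @param ... Unused.
#' @return The summary tibble (one row per domain plus the joint fit).
#' @method tidy rdc_domain_comparison
#' @export
tidy.rdc_domain_comparison <- function(x, ...) x$summary

#' @rdname tidy.rdc_domain_comparison
#' @method glance rdc_domain_comparison
#' @export
glance.rdc_domain_comparison <- function(x, ...) {
  sep <- x$summary[x$summary$domain != "joint", ]
  tibble(
    joint_r_factor = if ("joint" %in% x$summary$domain) {
      x$summary$r_factor[x$summary$domain == "joint"]
    } else NA_real_,
    weighted_separate_r_factor = if (nrow(sep) > 0) {
      sum(sep$r_factor * sep$n_rdcs) / sum(sep$n_rdcs)
    } else NA_real_,
    percent_increase = x$percent_increase,
    tensor_scalar_product = if (!is.null(x$tensor_difference)) {
      x$tensor_difference$scalar_product
    } else NA_real_
  )
}
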