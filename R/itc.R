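# Isothermal titration calorimetry: perfusion-cell concentration
# bookkeeping, the one-site (Wiseman) and sequential two-site
# binding-polynomial forward models, nonlinear isotherm fitting,
# equivalence-point location and dilution controls.
#
# Unit conventions: concentrations uM, volumes uL (injections) and mL
# (cell), heats ucal, enthalpies kcal/mol. These combine without
# conversion factors: kcal/mol * mL * uM = ucal.

#' Build an injection schedule
#'
#' @param volumes_uL Injection volumes, uL (> 0).
#' @param use_flag 0/1 per injection; 0 marks pre-injections (the small
#'   initial injections customarily discarded from fitting but kept in the
#'   concentration bookkeeping). Defaults to all 1.
#' @param cell_volume_mL Calorimeter cell volume, mL (default 1.4, typical
#'   for a VP-ITC class instrument).
#' @param syringe_conc_uM Titrant (syringe) concentration, uM.
#' @param cell_conc_uM Titrand (cell) concentration, uM.
#' @param temperature_C Cell temperature, C.
#' @return An `injection_schedule` list.
#' @export
injection_schedule <- function(volumes_uL, use_flag = NULL,
                               cell_volume_mL = 1.4,
                               syringe_conc_uM, cell_conc_uM,
                               temperature_C = 25) {
  if (any(volumes_uL <= 0)) abort("injection volumes must be positive")
  if (cell_volume_mL <= 0) abort("cell volume must be positive")
  if (is.null(use_flag)) use_flag <- rep(1L, length(volumes_uL))
  if (length(use_flag) != length(volumes_uL)) {
    abort("use_flag must match volumes in length")
  }
  if (sum(use_flag) < 1L) abort("at least one usable injection is required")
  structure(
    list(volumes_uL = volumes_uL, use_flag = as.integer(use_flag),
         cell_volume_mL = cell_volume_mL, syringe_conc_uM = syringe_conc_uM,
         cell_conc_uM = cell_conc_uM, temperature_C = temperature_C),
    class = "injection_schedule"
  )
}

#' Conventional schedule: small first injection(s), then 10 uL steps
#'
#' One (or more) 2 uL pre-injection flagged `use_flag = 0`, followed by
#' 10 uL injections, mirroring common calorimeter practice of at least 27
#' injections led by a small initial injection.
#'
#' @param n_injections Total number of injections (default 28).
#' @param n_pre Number of 2 uL pre-injections (default 1).
#' @param pre_uL,main_uL Pre- and main-injection volumes, uL.
#' @inheritParams injection_schedule
#' @return An `injection_schedule`.
#' @export
default_schedule <- function(syringe_conc_uM, cell_conc_uM,
                             n_injections = 28, n_pre = 1,
                             pre_uL = 2, main_uL = 10,
                             cell_volume_mL = 1.4, temperature_C = 25) {
  injection_schedule(
    volumes_uL = c(rep(pre_uL, n_pre), rep(main_uL, n_injections - n_pre)),
    use_flag = c(rep(0L, n_pre), rep(1L, n_injections - n_pre)),
    cell_volume_mL = cell_volume_mL,
    syringe_conc_uM = syringe_conc_uM, cell_conc_uM = cell_conc_uM,
    temperature_C = temperature_C
  )
}

#' Cell concentrations after the i-th injection
#'
#' Accounts for perfusion displacement: each injection of volume `v`
#' dilutes the existing cell contents by `(1 - v/V0)`; the titrand is only
#' diluted while freshly injected titrant is added and then diluted by the
#' same factor on subsequent injections.
#'
#' @param schedule An `injection_schedule`.
#' @param i Injection index (0 returns the nominal pre-titration cell).
#' @return List: `titrant_uM`, `titrand_uM`.
#' @export
concentrations_after_injection <- function(schedule, i) {
  n <- length(schedule$volumes_uL)
  if (i < 0 || i > n) abort(sprintf("injection index %d out of range 0..%d", i, n))
  cs <- concentration_series(schedule)
  if (i == 0) {
    list(titrant_uM = 0, titrand_uM = schedule$cell_conc_uM)
  } else {
    list(titrant_uM = cs$titrant_uM[i], titrand_uM = cs$titrand_uM[i])
  }
}

concentration_series <- function(schedule) {
  v0_uL <- schedule$cell_volume_mL * 1000
  x <- 0
  m <- schedule$cell_conc_uM
  n <- length(schedule$volumes_uL)
  xt <- numeric(n); mt <- numeric(n)
  for (i in seq_len(n)) {
    f <- 1 - schedule$volumes_uL[i] / v0_uL
    x <- x * f + schedule$syringe_conc_uM * schedule$volumes_uL[i] / v0_uL
    m <- m * f
    xt[i] <- x
    mt[i] <- m
  }
  tibble(
    injection = seq_len(n),
    volume_uL = schedule$volumes_uL,
    use_flag = schedule$use_flag,
    titrant_uM = xt,
    titrand_uM = mt,
    molar_ratio = ifelse(mt > 0, xt / mt, Inf)
  )
}

new_isotherm <- function(inj, cell_volume_mL, syringe_conc_uM, cell_conc_uM,
                         temperature_C) {
  sch <- injection_schedule(inj$volume_uL, inj$use_flag,
                            cell_volume_mL, syringe_conc_uM, cell_conc_uM,
                            temperature_C)
  cs <- concentration_series(sch)
  out <- tibble(
    injection = inj$injection,
    volume_uL = inj$volume_uL,
    heat_ucal = inj$heat_ucal,
    use_flag = as.integer(inj$use_flag),
    titrant_uM = cs$titrant_uM,
    titrand_uM = cs$titrand_uM,
    molar_ratio = cs$molar_ratio
  )
  attr(out, "cell_volume_mL") <- cell_volume_mL
  attr(out, "syringe_conc_uM") <- syringe_conc_uM
  attr(out, "cell_conc_uM") <- cell_conc_uM
  attr(out, "temperature_C") <- temperature_C
  class(out) <- c("itc_isotherm", class(tibble()))
  out
}

#' Schedule of an isotherm
#'
#' @param isotherm An `itc_isotherm` tibble.
#' @return The underlying `injection_schedule`.
#' @export
isotherm_schedule <- function(isotherm) {
  injection_schedule(
    volumes_uL = isotherm$volume_uL, use_flag = isotherm$use_flag,
    cell_volume_mL = attr(isotherm, "cell_volume_mL"),
    syringe_conc_uM = attr(isotherm, "syringe_conc_uM"),
    cell_conc_uM = attr(isotherm, "cell_conc_uM"),
    temperature_C = attr(isotherm, "temperature_C")
  )
}

# cumulative-to-per-injection heats with the midpoint displacement
# correction: dq_i = Q_i - Q_(i-1) + (dV_i/V0) (Q_i + Q_(i-1))/2
per_injection_heats <- function(q_cum, volumes_uL, cell_volume_mL,
                                displacement = TRUE) {
  q_prev <- c(0, q_cum[-length(q_cum)])
  dq <- q_cum - q_prev
  if (displacement) {
    dq <- dq + (volumes_uL / (cell_volume_mL * 1000)) * (q_cum + q_prev) / 2
  }
  dq
}

#' One-site (Wiseman) isotherm forward model
#'
#' Bound titrant after each injection from the exact depletion quadratic
#' with site concentration `n * [titrand]`; per-injection heat is the
#' change in cell heat content plus the midpoint displacement correction.
#' Exothermic binding gives negative heats.
#'
#' @param params List with `n` (sites per cell molecule), `Kd_uM`,
#'   `dH_kcal` (kcal/mol) and optional `q_offset_ucal` (per-injection
#'   offset, default 0).
#' @param schedule An `injection_schedule`.
#' @param displacement Apply the midpoint displacement correction
#'   (default TRUE).
#' @return Numeric vector of per-injection heats, ucal.
#' @export
heats_one_site <- function(params, schedule, displacement = TRUE) {
  stopifnot(params$n > 0, params$Kd_uM > 0)
  q_off <- params$q_offset_ucal %||% 0
  cs <- concentration_series(schedule)
  sites <- params$n * cs$titrand_uM
  s <- cs$titrant_uM + sites + params$Kd_uM
  bound <- (s - sqrt(pmax(0, s^2 - 4 * cs$titrant_uM * sites))) / 2
  q_cum <- params$dH_kcal * schedule$cell_volume_mL * bound
  per_injection_heats(q_cum, schedule$volumes_uL, schedule$cell_volume_mL,
                      displacement) + q_off
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# free titrant concentration from sequential two-site mass balance,
# bracketed monotone root finding to 1e-12 relative tolerance
free_titrant_two_site <- function(x_total, m_total, k1, k2) {
  if (x_total <= 0) return(0)
  g <- function(x) {
    p <- 1 + k1 * x + k1 * k2 * x^2
    x + m_total * (k1 * x + 2 * k1 * k2 * x^2) / p - x_total
  }
  x <- uniroot(g, lower = 0, upper = x_total,
               tol = .Machine$double.eps * max(1, x_total))$root
  # one Newton polish to push the residual to machine precision
  h <- 1e-7 * max(x, 1e-12)
  dg <- (g(x + h) - g(x - h)) / (2 * h)
  if (is.finite(dg) && dg > 0) x <- max(0, min(x_total, x - g(x) / dg))
  x
}

#' Sequential two-site isotherm forward model
#'
#' Binding polynomial `P = 1 + K1 [X] + K1 K2 [X]^2` over the ligation
#' states of the cell molecule; the free titrant `[X]` is solved per
#' injection from mass balance by bracketed root finding, and the
#' cumulative heat is `V0 M_t (dH1 th1 + (dH1 + dH2) th2)` with `th1`,
#' `th2` the singly/doubly bound species fractions. Reduces exactly to the
#' one-site model with `n = 1` as `K2 -> 0`.
#'
#' @param params List with `Kd1_uM`, `Kd2_uM` (stepwise macroscopic
#'   dissociation constants, uM), `dH1_kcal`, `dH2_kcal` (kcal/mol per
#'   step) and optional `q_offset_ucal`.
#' @param schedule An `injection_schedule`.
#' @param displacement Apply the midpoint displacement correction.
#' @return Numeric vector of per-injection heats, ucal.
#' @export
heats_two_site <- function(params, schedule, displacement = TRUE) {
  stopifnot(params$Kd1_uM > 0, params$Kd2_uM > 0)
  q_off <- params$q_offset_ucal %||% 0
  k1 <- 1 / params$Kd1_uM
  k2 <- 1 / params$Kd2_uM
  cs <- concentration_series(schedule)
  q_cum <- vapply(seq_len(nrow(cs)), function(i) {
    x <- free_titrant_two_site(cs$titrant_uM[i], cs$titrand_uM[i], k1, k2)
    p <- 1 + k1 * x + k1 * k2 * x^2
    th1 <- k1 * x / p
    th2 <- k1 * k2 * x^2 / p
    schedule$cell_volume_mL * cs$titrand_uM[i] *
      (params$dH1_kcal * th1 + (params$dH1_kcal + params$dH2_kcal) * th2)
  }, numeric(1))
  per_injection_heats(q_cum, schedule$volumes_uL, schedule$cell_volume_mL,
                      displacement) + q_off
}

#' Independent two-site isotherm forward model
#'
#' Two independent classes of one site each on the cell molecule; provided
#' as an alternative parameterisation of multi-site binding.
#'
#' @inheritParams heats_two_site
#' @return Numeric vector of per-injection heats, ucal.
#' @export
heats_two_site_independent <- function(params, schedule, displacement = TRUE) {
  stopifnot(params$Kd1_uM > 0, params$Kd2_uM > 0)
  q_off <- params$q_offset_ucal %||% 0
  k1 <- 1 / params$Kd1_uM
  k2 <- 1 / params$Kd2_uM
  cs <- concentration_series(schedule)
  q_cum <- vapply(seq_len(nrow(cs)), function(i) {
    xt <- cs$titrant_uM[i]
    mt <- cs$titrand_uM[i]
    if (xt <= 0) return(0)
    g <- function(x) x + mt * (k1 * x / (1 + k1 * x) + k2 * x / (1 + k2 * x)) - xt
    x <- uniroot(g, lower = 0, upper = xt, tol = 1e-12 * max(1, xt))$root
    schedule$cell_volume_mL * mt *
      (params$dH1_kcal * k1 * x / (1 + k1 * x) +
         params$dH2_kcal * k2 * x / (1 + k2 * x))
  }, numeric(1))
  per_injection_heats(q_cum, schedule$volumes_uL, schedule$cell_volume_mL,
                      displacement) + q_off
}

itc_forward <- function(model_kind) {
  switch(model_kind,
    one_site = heats_one_site,
    two_site_sequential = heats_two_site,
    two_site_independent = heats_two_site_independent,
    abort(sprintf("unknown model '%s'", model_kind))
  )
}

#' Fit a binding model to an ITC isotherm
#'
#' Levenberg-Marquardt least squares of the chosen forward model against
#' the usable injections (`use_flag == 1`; pre-injections stay in the
#' concentration bookkeeping but not in the fit). Default initial values:
#' `n` from the molar ratio at the steepest heat change, `dH` from the
#' first usable heat per mole injected, and `Kd` from a small multi-start
#' over plausible c-values.
#'
#' @param isotherm An `itc_isotherm`.
#' @param model_kind `"one_site"`, `"two_site_sequential"` or
#'   `"two_site_independent"`.
#' @param init Optional named list of start values overriding the
#'   heuristics.
#' @param fit_offset Also fit a constant per-injection heat offset.
#' @param control Optional dilution-control isotherm; its mean heat is
#'   subtracted from the data before fitting (see [dilution_control()]).
#' @return An `itc_fit`: `params` tibble (term, estimate, se), `model`,
#'   `residuals`, `heats_fit`, `c_value` (one-site), `converged`,
#'   `residual_norm`, `n_used`.
#' @export
fit_isotherm <- function(isotherm, model_kind = c("one_site",
                                                  "two_site_sequential",
                                                  "two_site_independent"),
                         init = NULL, fit_offset = FALSE, control = NULL) {
  model_kind <- match.arg(model_kind)
  sch <- isotherm_schedule(isotherm)
  usable <- isotherm$use_flag == 1L
  if (sum(usable) < 8L) abort("need at least 8 usable injections")
  y <- isotherm$heat_ucal
  if (!is.null(control)) {
    y <- y - dilution_control(control)$mean_heat_ucal
  }
  y_use <- y[usable]
  if (max(y_use) - min(y_use) < 1e-9 * max(1, max(abs(y_use)))) {
    abort("flat isotherm: binding parameters are unidentifiable")
  }
  m0 <- sch$cell_conc_uM
  ratios <- isotherm$molar_ratio

  # heuristics: n at steepest change of heat vs ratio; dH from the first
  # usable injection's heat per mole injected
  d1 <- diff(y_use) / pmax(diff(ratios[usable]), 1e-12)
  n_init <- ratios[usable][which.max(abs(d1))]
  if (!is.finite(n_init) || n_init <= 0) n_init <- 1
  first <- which(usable)[1]
  nmol_first <- sch$volumes_uL[first] * sch$syringe_conc_uM * 1e-3  # nmol
  dh_init <- y_use[1] / nmol_first  # ucal/nmol = kcal/mol

  fwd <- itc_forward(model_kind)
  resid_fn <- function(par) {
    p <- par_to_params(par)
    y_use - fwd(p, sch)[usable]
  }

  if (model_kind == "one_site") {
    par_to_params <- function(par) list(
      n = exp(par[["log_n"]]), Kd_uM = exp(par[["log_Kd"]]),
      dH_kcal = par[["dH"]],
      q_offset_ucal = if (fit_offset) par[["q0"]] else 0
    )
    kd_grid <- m0 * c(0.01, 0.1, 1, 10)
    starts <- lapply(kd_grid, function(kd) {
      s <- c(log_n = log(n_init), log_Kd = log(kd), dH = dh_init)
      if (fit_offset) s <- c(s, q0 = 0)
      s
    })
  } else {
    par_to_params <- function(par) list(
      Kd1_uM = exp(par[["log_Kd1"]]), Kd2_uM = exp(par[["log_Kd2"]]),
      dH1_kcal = par[["dH1"]], dH2_kcal = par[["dH2"]],
      q_offset_ucal = if (fit_offset) par[["q0"]] else 0
    )
    kd_grid <- m0 * c(0.01, 0.1, 1)
    starts <- lapply(kd_grid, function(kd) {
      s <- c(log_Kd1 = log(kd), log_Kd2 = log(kd * 3),
             dH1 = dh_init, dH2 = dh_init)
      if (fit_offset) s <- c(s, q0 = 0)
      s
    })
  }
  if (!is.null(init)) {
    starts <- list(init_to_par(init, model_kind, fit_offset))
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) abort("isotherm fit failed from every start")
  if (best$info < 1 || best$info > 4) {
    abort(sprintf("isotherm fit did not converge: %s (last iterate: %s)",
                  best$message,
                  paste(sprintf("%s=%.4g", names(best$par), unlist(best$par)),
                        collapse = ", ")))
  }
  par <- unlist(best$par)
  p <- par_to_params(par)
  se_raw <- tryCatch(sqrt(diag(vcov(best))), error = function(e) {
    rep(NA_real_, length(par))
  })
  names(se_raw) <- names(par)

  if (model_kind == "one_site") {
    params <- tibble(
      term = c("n", "Kd_uM", "dH_kcal", if (fit_offset) "q_offset_ucal"),
      estimate = c(p$n, p$Kd_uM, p$dH_kcal, if (fit_offset) p$q_offset_ucal),
      se = c(p$n * se_raw[["log_n"]], p$Kd_uM * se_raw[["log_Kd"]],
             se_raw[["dH"]], if (fit_offset) se_raw[["q0"]])
    )
    c_value <- p$n * m0 / p$Kd_uM
    if (c_value < 1 || c_value > 1000) {
      warn(sprintf("Wiseman c = %.2f outside [1, 1000]; parameters may be poorly determined", c_value))
    }
  } else {
    params <- tibble(
      term = c("Kd1_uM", "Kd2_uM", "dH1_kcal", "dH2_kcal",
               if (fit_offset) "q_offset_ucal"),
      estimate = c(p$Kd1_uM, p$Kd2_uM, p$dH1_kcal, p$dH2_kcal,
                   if (fit_offset) p$q_offset_ucal),
      se = c(p$Kd1_uM * se_raw[["log_Kd1"]], p$Kd2_uM * se_raw[["log_Kd2"]],
             se_raw[["dH1"]], se_raw[["dH2"]], if (fit_offset) se_raw[["q0"]])
    )
    c_value <- NA_real_
  }
  heats_fit <- fwd(p, sch)
  out <- list(
    model = model_kind, params = params, param_list = p,
    heats_fit = heats_fit,
    residuals = tibble(injection = isotherm$injection,
                       molar_ratio = ratios,
                       heat_ucal = y,
                       fitted_ucal = heats_fit,
                       residual_ucal = y - heats_fit,
                       used = usable),
    c_value = c_value,
    residual_norm = sqrt(best$deviance),
    n_used = sum(usable),
    converged = TRUE,
    isotherm = isotherm
  )
  class(out) <- "itc_fit"
  out
}

init_to_par <- function(init, model_kind, fit_offset) {
  if (model_kind == "one_site") {
    s <- c(log_n = log(init$n), log_Kd = log(init$Kd_uM), dH = init$dH_kcal)
  } else {
    s <- c(log_Kd1 = log(init$Kd1_uM), log_Kd2 = log(init$Kd2_uM),
           dH1 = init$dH1_kcal, dH2 = init$dH2_kcal)
  }
  if (fit_offset) s <- c(s, q0 = init$q_offset_ucal %||% 0)
  s
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("<itc_fit> model = %s, n_used = %d, residual norm = %.4g ucal\n",
              x$model, x$n_used, x$residual_norm))
  print(as.data.frame(x$params), row.names = FALSE)
  if (!is.na(x$c_value)) cat(sprintf("Wiseman c = %.1f\n", x$c_value))
  invisible(x)
}

#' Molar ratio at the isotherm transition midpoint
#'
#' Locates the extremum of the discrete first derivative of heat versus
#' molar ratio among the usable injections and refines it by local
#' quadratic interpolation. For tight binding, the midpoint falls at the
#' stoichiometric equivalence ratio (n for one site, 2 for two sequential
#' sites per cell molecule).
#'
#' @param isotherm An `itc_isotherm`.
#' @return List: `ratio` (NA when no transition), `no_transition` flag,
#'   `spacing` (local molar-ratio grid spacing at the transition).
#' @export
equivalence_ratio <- function(isotherm) {
  use <- isotherm$use_flag == 1L
  if (sum(use) < 5L) abort("need at least 5 usable injections")
  x <- isotherm$molar_ratio[use]
  y <- isotherm$heat_ucal[use]
  if (diff(range(y)) < max(1e-9, 0.02 * max(abs(y), 1e-12))) {
    return(list(ratio = NA_real_, no_transition = TRUE, spacing = NA_real_))
  }
  xm <- (x[-1] + x[-length(x)]) / 2
  d <- diff(y) / diff(x)
  k <- which.max(abs(d))
  ratio <- xm[k]
  if (k > 1L && k < length(d)) {
    # quadratic through the three |derivative| points around the extremum
    xs <- xm[(k - 1):(k + 1)]
    ys <- abs(d)[(k - 1):(k + 1)]
    denom <- (xs[1] - xs[2]) * (xs[1] - xs[3]) * (xs[2] - xs[3])
    a <- (xs[3] * (ys[2] - ys[1]) + xs[2] * (ys[1] - ys[3]) +
            xs[1] * (ys[3] - ys[2])) / denom
    b <- (xs[3]^2 * (ys[1] - ys[2]) + xs[2]^2 * (ys[3] - ys[1]) +
            xs[1]^2 * (ys[2] - ys[3])) / denom
    if (a < 0) {
      vert <- -b / (2 * a)
      if (vert >= xs[1] && vert <= xs[3]) ratio <- vert
    }
  }
  list(ratio = ratio, no_transition = FALSE,
       spacing = mean(diff(x[max(1, k - 1):min(length(x), k + 2)])))
}

#' Assess a dilution (buffer-only) control
#'
#' @param isotherm An `itc_isotherm` measured with no titrand in the cell
#'   (or user-designated control run).
#' @param threshold_ucal Verdict threshold on the mean per-injection heat
#'   (default 0.5 ucal).
#' @return List: `mean_heat_ucal`, `sd_heat_ucal`, `negligible`.
#' @export
dilution_control <- function(isotherm, threshold_ucal = 0.5) {
  use <- isotherm$use_flag == 1L
  h <- isotherm$heat_ucal[use]
  m <- mean(h)
  list(mean_heat_ucal = m, sd_heat_ucal = sd(h),
       negligible = abs(m) < threshold_ucal)
}
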