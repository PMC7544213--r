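# Synthetic-data generators: every input class of the analysis chain
# (RDC tables, relaxation tables / decay series, HSQC titrations, ITC
# isotherms) produced from the corresponding forward model plus Gaussian
# noise, deterministically under a fixed seed. Feeding a generator's
# output to its matching analysis stage at zero noise recovers the
# generating parameters (exactly for the linear RDC fit and ITC, within
# the closed form's approximation for tau_c).

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Generate an RDC table from a structure and alignment tensor(s)
#'
#' `D_obs` is back-calculated from the tensor applied to the structure's
#' N-H unit vectors, plus independent Gaussian noise. When the structure
#' carries domain labels and `tensor` is a named list (one tensor per
#' domain label), each domain gets its own tensor - the generating picture
#' for domains that do not share an alignment frame.
#'
#' @param structure Structure tibble with amide H atoms (or use
#'   `build_h = TRUE`).
#' @param tensor An `alignment_tensor`, or a named list of them keyed by
#'   domain label.
#' @param noise_sd Gaussian noise standard deviation, Hz (default 0).
#' @param seed Integer seed for reproducible noise.
#' @param residues Optional residue subset.
#' @param build_h Build missing amide protons.
#' @return An RDC tibble (`residue_number`, `D_obs_Hz`, `D_err_Hz`,
#'   `domain`).
#' @export
#' @examples
#' s <- gen_structure(20, "helix")
#' gen_rdc_set(s, alignment_tensor(10.6, 0.23), noise_sd = 1, seed = 1)
gen_rdc_set <- function(structure, tensor, noise_sd = 0, seed = NULL,
                        residues = NULL, build_h = FALSE) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  vec <- nh_unit_vectors(structure, residues, build_h = build_h)
  dom <- domain_of_residue(structure, vec$residue_number)
  if (inherits(tensor, "alignment_tensor")) {
    vec <- back_calc_rdc(tensor, vec)
  } else {
    if (is.null(names(tensor)) || !all(dom %in% names(tensor))) {
      abort("per-domain tensors must be a named list covering every domain label")
    }
    vec$D_calc_Hz <- NA_real_
    for (lab in unique(dom)) {
      sel <- dom == lab
      vec$D_calc_Hz[sel] <- back_calc_rdc(tensor[[lab]], vec[sel, ])$D_calc_Hz
    }
  }
  d_obs <- with_seed(seed, vec$D_calc_Hz + rnorm(nrow(vec), 0, noise_sd))
  tibble(
    residue_number = vec$residue_number,
    D_obs_Hz = d_obs,
    D_err_Hz = if (noise_sd > 0) noise_sd else NA_real_,
    domain = dom
  )
}

#' Generate a per-residue relaxation table or decay series
#'
#' Rates come from the rigid/model-free forward model
#' ([forward_relaxation_rates()]) with an optional per-residue order
#' parameter profile; decay mode emits `I0 exp(-R t)` intensities at the
#' bundled delay schedules ([relaxation_delays]) for the given field.
#'
#' @param tau_c_ns Overall correlation time, ns.
#' @param field_MHz_1H 1H field, MHz (500 and 850 select their bundled
#'   delay lists in decay mode).
#' @param n_residues Number of residues.
#' @param S2_profile Optional numeric vector (length `n_residues`) of
#'   order parameters; default rigid (all 1).
#' @param tau_e_ns Internal correlation time used wherever `S2 < 1`
#'   (default 0.8 ns, typical of disordered tails).
#' @param noise_sd Gaussian noise sd added to each of R1, R2 (s^-1) and
#'   hetNOE (dimensionless), or to decay intensities (fraction of I0) in
#'   decay mode.
#' @param seed Integer seed.
#' @param mode `"rates"` (default) or `"decays"`.
#' @param I0 Reference intensity for decay mode.
#' @return Rates mode: tibble `residue_number`, `R1_s`, `R2_s`, `hetNOE`.
#'   Decay mode: tibble `residue_number`, `experiment` (`"R1"`/`"R2"`),
#'   `delay_ms`, `intensity`.
#' @export
gen_relaxation_set <- function(tau_c_ns, field_MHz_1H, n_residues,
                               S2_profile = NULL, tau_e_ns = 0.8,
                               noise_sd = 0, seed = NULL,
                               mode = c("rates", "decays"), I0 = 1e6) {
  mode <- match.arg(mode)
  if (tau_c_ns <= 0) abort("tau_c must be positive")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  s2 <- S2_profile %||% rep(1, n_residues)
  if (length(s2) != n_residues) abort("S2_profile must have n_residues values")
  base <- purrr::map_dfr(seq_len(n_residues), function(i) {
    r <- forward_relaxation_rates(tau_c_ns, field_MHz_1H, S2 = s2[i],
                                  tau_e_ns = if (s2[i] < 1) tau_e_ns else 0)
    tibble(residue_number = i, R1_s = r$R1_s, R2_s = r$R2_s, hetNOE = r$NOE)
  })
  if (mode == "rates") {
    out <- with_seed(seed, mutate(
      base,
      R1_s = .data$R1_s + rnorm(n_residues, 0, noise_sd),
      R2_s = .data$R2_s + rnorm(n_residues, 0, noise_sd),
      hetNOE = .data$hetNOE + rnorm(n_residues, 0, noise_sd)
    ))
    attr(out, "relaxation_mode") <- "rates"
    attr(out, "tau_c_ns") <- tau_c_ns
    attr(out, "field_MHz_1H") <- field_MHz_1H
    return(out)
  }
  key <- if (abs(field_MHz_1H - 850) < abs(field_MHz_1H - 500)) "850" else "500"
  sched <- list(R1 = relaxation_delays[[paste0("r1_", key)]],
                R2 = relaxation_delays[[paste0("r2_", key)]])
  out <- purrr::map_dfr(c("R1", "R2"), function(exp_name) {
    delays <- sched[[exp_name]]
    purrr::map_dfr(seq_len(n_residues), function(i) {
      rate <- if (exp_name == "R1") base$R1_s[i] else base$R2_s[i]
      tibble(residue_number = i, experiment = exp_name, delay_ms = delays,
             intensity = I0 * exp(-rate * delays / 1000))
    })
  })
  out <- with_seed(seed, mutate(
    out, intensity = .data$intensity + rnorm(nrow(out), 0, noise_sd * I0)
  ))
  attr(out, "relaxation_mode") <- "decays"
  attr(out, "tau_c_ns") <- tau_c_ns
  attr(out, "field_MHz_1H") <- field_MHz_1H
  out
}

#' Exchange specification for titration simulation
#'
#' @param Kd_uM Dissociation constant, uM.
#' @param delta_bound Tibble with `residue_number`, `ddH_bound_ppm`,
#'   `ddN_bound_ppm`: the fully bound-state shift changes per residue.
#' @param kex_s Exchange rate, s^-1 (optional; required for broadening).
#' @param R2_0_s Baseline transverse rate used as linewidth proxy
#'   (default 20 s^-1).
#' @return An `exchange_spec` list.
#' @export
exchange_spec <- function(Kd_uM, delta_bound, kex_s = NULL, R2_0_s = 20) {
  if (Kd_uM <= 0) abort("Kd must be positive")
  if (!is.null(kex_s) && kex_s <= 0) abort("kex must be positive when given")
  delta_bound <- as_tibble(delta_bound)
  stopifnot(all(c("residue_number", "ddH_bound_ppm", "ddN_bound_ppm") %in%
                  names(delta_bound)))
  structure(list(Kd_uM = Kd_uM, delta_bound = delta_bound,
                 kex_s = kex_s, R2_0_s = R2_0_s),
            class = "exchange_spec")
}

#' Simulate an HSQC titration series
#'
#' Observed shifts follow the fast-exchange population average
#' `d_obs = (1 - fb) d_free + fb d_bound` with the bound fraction from the
#' single-site depletion quadratic. When `exchange$kex_s` is set,
#' intensities are attenuated by `R2_0 / (R2_0 + Rex)` with the
#' fast-exchange-limit `Rex = pf pb dw^2 / kex`, `dw` (rad/s) taken from
#' the larger of the two dimensions' shift differences - reproducing the
#' shift-broaden-resharpen pattern of intermediate-fast exchange.
#'
#' @param ref Reference peak list (the `ratio = 0` point).
#' @param exchange An [exchange_spec()].
#' @param protein_conc_uM Total protein, uM (default 200).
#' @param ligand_ratios Ligand:protein molar ratios; non-negative,
#'   increasing, starting at 0 (default `c(0, 0.25, 0.5, 1, 2, 3)`,
#'   ending at the 1:3 endpoint where a weak binder approaches
#'   saturation).
#' @param broadening Simulate exchange broadening (requires `kex_s`).
#' @param noise_sd Gaussian shift noise, ppm, added to both dimensions.
#' @param seed Integer seed.
#' @param field_MHz_1H 1H field for converting ppm to rad/s (default 850).
#' @return Titration tibble: `residue_number`, `residue_name`, `dH_ppm`,
#'   `dN_ppm`, `intensity`, `ratio`; generating parameters stored in
#'   attributes.
#' @export
gen_titration <- function(ref, exchange, protein_conc_uM = 200,
                          ligand_ratios = c(0, 0.25, 0.5, 1, 2, 3),
                          broadening = !is.null(exchange$kex_s),
                          noise_sd = 0, seed = NULL, field_MHz_1H = 850) {
  if (any(ligand_ratios < 0)) abort("ratios must be non-negative")
  if (is.unsorted(ligand_ratios, strictly = TRUE)) {
    abort("ratios must be strictly increasing")
  }
  if (ligand_ratios[1] != 0) abort("the first ratio must be 0 (reference)")
  if (broadening && is.null(exchange$kex_s)) {
    abort("broadening requested but exchange$kex_s is not set")
  }
  db <- exchange$delta_bound
  dat <- left_join(ref, db, by = "residue_number")
  dat$ddH_bound_ppm[is.na(dat$ddH_bound_ppm)] <- 0
  dat$ddN_bound_ppm[is.na(dat$ddN_bound_ppm)] <- 0
  nu_h <- field_MHz_1H * 1e6
  nu_n <- nu_N_from_field(field_MHz_1H)
  out <- purrr::map_dfr(ligand_ratios, function(r) {
    l_tot <- r * protein_conc_uM
    fb <- if (r == 0) 0 else fraction_bound(protein_conc_uM, l_tot, exchange$Kd_uM)
    mult <- 1
    if (broadening) {
      dw <- 2 * pi * pmax(abs(dat$ddH_bound_ppm) * nu_h,
                          abs(dat$ddN_bound_ppm) * nu_n) * 1e-6
      rex <- (1 - fb) * fb * dw^2 / exchange$kex_s
      mult <- exchange$R2_0_s / (exchange$R2_0_s + rex)
    }
    tibble(
      residue_number = dat$residue_number,
      residue_name = dat$residue_name,
      dH_ppm = dat$dH_ppm + fb * dat$ddH_bound_ppm,
      dN_ppm = dat$dN_ppm + fb * dat$ddN_bound_ppm,
      intensity = dat$intensity * mult,
      ratio = r
    )
  })
  if (noise_sd > 0) {
    out <- with_seed(seed, mutate(
      out,
      dH_ppm = .data$dH_ppm + rnorm(nrow(out), 0, noise_sd),
      dN_ppm = .data$dN_ppm + rnorm(nrow(out), 0, noise_sd)
    ))
  }
  attr(out, "protein_conc_uM") <- protein_conc_uM
  attr(out, "Kd_uM") <- exchange$Kd_uM
  attr(out, "field_MHz_1H") <- field_MHz_1H
  class(out) <- c("titration_series", class(tibble()))
  out
}

#' Simulate an ITC isotherm
#'
#' Heats from the chosen forward model plus Gaussian noise; pre-injections
#' keep `use_flag = 0` as set in the schedule.
#'
#' @param params Parameter list for the forward model (see
#'   [heats_one_site()] / [heats_two_site()]).
#' @param schedule An [injection_schedule()].
#' @param model_kind `"one_site"`, `"two_site_sequential"` or
#'   `"two_site_independent"`.
#' @param noise_sd Gaussian heat noise, ucal.
#' @param seed Integer seed.
#' @return An `itc_isotherm` tibble.
#' @export
#' @examples
#' sch <- default_schedule(syringe_conc_uM = 7000, cell_conc_uM = 800)
#' iso <- gen_isotherm(list(n = 0.9, Kd_uM = 139, dH_kcal = -5), sch)
gen_isotherm <- function(params, schedule,
                         model_kind = c("one_site", "two_site_sequential",
                                        "two_site_independent"),
                         noise_sd = 0, seed = NULL) {
  model_kind <- match.arg(model_kind)
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  heats <- itc_forward(model_kind)(params, schedule)
  heats <- with_seed(seed, heats + rnorm(length(heats), 0, noise_sd))
  new_isotherm(
    tibble(injection = seq_along(heats), volume_uL = schedule$volumes_uL,
           heat_ucal = heats, use_flag = schedule$use_flag),
    cell_volume_mL = schedule$cell_volume_mL,
    syringe_conc_uM = schedule$syringe_conc_uM,
    cell_conc_uM = schedule$cell_conc_uM,
    temperature_C = schedule$temperature_C
  )
}
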