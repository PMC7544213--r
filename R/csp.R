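# Chemical-shift-perturbation analysis: the weighted-average CSP, peak
# matching, classification of large shifts, the single-site depletion
# binding curve and global/per-residue Kd fitting of HSQC titrations.

#' Weighted-average amide chemical shift perturbation
#'
#' `csp = sqrt( (dH^2 + (0.14 dN)^2) / 2 )` with the conventional 0.14
#' nitrogen weight accounting for the wider 15N shift range.
#'
#' @param delta_dH,delta_dN 1H and 15N shift differences, ppm.
#' @param n_weight Nitrogen weight (default 0.14; override only
#'   deliberately, as the default is the conventional choice all thresholds
#'   here assume).
#' @return Combined CSP in ppm.
#' @export
#' @examples
#' csp_avg(0.05, 0.5)  # 0.0608
csp_avg <- function(delta_dH, delta_dN, n_weight = 0.14) {
  sqrt((delta_dH^2 + (n_weight * delta_dN)^2) / 2)
}

#' Match peaks between two lists by weighted shift distance
#'
#' Greedy nearest-neighbour assignment in weighted ppm space: all candidate
#' pairs are ranked by ascending [csp_avg()] distance and accepted when
#' neither peak is already used and the distance is within `max_dist_ppm`.
#' Intended for transferring assignments when peak positions have moved.
#'
#' @param ref,other Peak-list tibbles ([read_peaklist()]).
#' @param max_dist_ppm Hard cutoff on the weighted distance (default 0.1).
#' @param n_weight Nitrogen weight for the distance.
#' @return A tibble with `ref_residue`, `other_residue` (NA when
#'   unmatched), `distance_ppm`, `matched`.
#' @export
match_peaks <- function(ref, other, max_dist_ppm = 0.1, n_weight = 0.14) {
  if (nrow(ref) == 0L || nrow(other) == 0L) abort("both peak lists must be non-empty")
  dmat <- outer(seq_len(nrow(ref)), seq_len(nrow(other)),
                function(i, j) csp_avg(other$dH_ppm[j] - ref$dH_ppm[i],
                                       other$dN_ppm[j] - ref$dN_ppm[i],
                                       n_weight))
  ord <- order(dmat)
  used_ref <- logical(nrow(ref))
  used_other <- logical(nrow(other))
  pair_other <- rep(NA_integer_, nrow(ref))
  pair_dist <- rep(NA_real_, nrow(ref))
  for (k in ord) {
    if (dmat[k] > max_dist_ppm) break
    i <- (k - 1L) %% nrow(ref) + 1L
    j <- (k - 1L) %/% nrow(ref) + 1L
    if (used_ref[i] || used_other[j]) next
    used_ref[i] <- TRUE
    used_other[j] <- TRUE
    pair_other[i] <- j
    pair_dist[i] <- dmat[k]
  }
  tibble(
    ref_residue = ref$residue_number,
    other_residue = ifelse(is.na(pair_other), NA_integer_,
                           other$residue_number[pair_other]),
    distance_ppm = pair_dist,
    matched = !is.na(pair_other)
  )
}

#' Per-residue chemical shift perturbations between two spectra
#'
#' Residues are paired by residue number (use [match_peaks()] first when
#' assignments cannot be trusted). Shift differences are stored signed as
#' `other - ref`; the combined CSP uses their magnitudes.
#'
#' @param ref,other Peak-list tibbles.
#' @param n_weight Nitrogen weight for [csp_avg()].
#' @return A `csp_profile` tibble: `residue_number`, `delta_dH`,
#'   `delta_dN`, `csp_avg` (ppm), `matched`. Residues present in only one
#'   list are flagged unmatched and carry no CSP.
#' @export
csp_per_residue <- function(ref, other, n_weight = 0.14) {
  all_res <- sort(union(ref$residue_number, other$residue_number))
  i_ref <- match(all_res, ref$residue_number)
  i_oth <- match(all_res, other$residue_number)
  matched <- !is.na(i_ref) & !is.na(i_oth)
  ddh <- other$dH_ppm[i_oth] - ref$dH_ppm[i_ref]
  ddn <- other$dN_ppm[i_oth] - ref$dN_ppm[i_ref]
  out <- tibble(
    residue_number = all_res,
    delta_dH = ifelse(matched, ddh, NA_real_),
    delta_dN = ifelse(matched, ddn, NA_real_),
    csp_avg = ifelse(matched, csp_avg(ddh, ddn, n_weight), NA_real_),
    matched = matched
  )
  class(out) <- c("csp_profile", class(out))
  out
}

#' Residues with large chemical shift perturbations
#'
#' @param profile A `csp_profile` tibble.
#' @param threshold_ppm Strict threshold; residues with
#'   `csp_avg > threshold_ppm` are returned (default 0.025 ppm, the
#'   conventional cutoff for calling a perturbation large).
#' @return Integer vector of residue numbers.
#' @export
classify_large <- function(profile, threshold_ppm = 0.025) {
  sel <- !is.na(profile$csp_avg) & profile$csp_avg > threshold_ppm
  profile$residue_number[sel]
}

#' Fraction of protein bound under ligand depletion
#'
#' Single-site mass balance solved exactly:
#' `fb = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / (2 P)`.
#'
#' @param P_total_uM Total protein concentration, uM (> 0).
#' @param L_total_uM Total ligand concentration, uM (vectorised).
#' @param Kd_uM Dissociation constant, uM (> 0).
#' @return Fraction of protein bound, in `[0, 1]`.
#' @export
#' @examples
#' fraction_bound(50, 50, 50)  # 0.382
fraction_bound <- function(P_total_uM, L_total_uM, Kd_uM) {
  if (P_total_uM <= 0) abort("P_total must be positive (fraction undefined at P = 0)")
  if (Kd_uM <= 0) abort("Kd must be positive")
  if (any(L_total_uM < 0)) abort("ligand concentrations must be non-negative")
  s <- P_total_uM + L_total_uM + Kd_uM
  disc <- pmax(0, s^2 - 4 * P_total_uM * L_total_uM)
  fb <- (s - sqrt(disc)) / (2 * P_total_uM)
  pmin(pmax(fb, 0), 1)
}

titration_ligand_totals <- function(series, P_total_uM, L_totals_uM = NULL) {
  if (!is.null(L_totals_uM)) return(L_totals_uM)
  ratios <- sort(unique(series$ratio))
  ratios * P_total_uM
}

#' Fit a dissociation constant to an HSQC titration
#'
#' Nonlinear least squares on the fast-exchange observed shift
#' `d_obs(L) = d_free + (d_bound - d_free) fb(P, L, Kd)` with `fb` from the
#' depletion quadratic ([fraction_bound()]). In `"global"` mode one Kd is
#' shared across all residues while the bound-state endpoints are
#' per-residue (profiled out linearly, so the optimisation is
#' one-dimensional in log Kd); `"per_residue"` mode fits each residue
#' separately as a diagnostic. 15N residuals are weighted by the 0.14
#' nitrogen factor so both dimensions contribute on a common ppm scale.
#'
#' @param series Titration tibble: columns `residue_number`, `dH_ppm`,
#'   `dN_ppm`, `ratio` (ligand:protein molar ratio; the reference point is
#'   `ratio == 0`), e.g. from [gen_titration()].
#' @param P_total_uM Total protein concentration, uM.
#' @param L_totals_uM Optional explicit total-ligand series, uM (defaults
#'   to `ratio * P_total_uM`).
#' @param mode `"global"` (default) or `"per_residue"`.
#' @param n_weight Nitrogen weight.
#' @return A `binding_curve_fit` object; see [tidy.binding_curve_fit()].
#' @export
fit_kd_from_titration <- function(series, P_total_uM, L_totals_uM = NULL,
                                  mode = c("global", "per_residue"),
                                  n_weight = 0.14) {
  mode <- match.arg(mode)
  ratios <- sort(unique(series$ratio))
  if (length(ratios) < 3L) abort("need at least 3 titration points")
  if (min(ratios) != 0) abort("the reference point (ratio 0) is required")
  l_tot <- titration_ligand_totals(series, P_total_uM, L_totals_uM)
  if (length(l_tot) != length(ratios)) {
    abort("L_totals_uM must have one value per titration point")
  }

  wide <- series %>%
    select("residue_number", "dH_ppm", "dN_ppm", "ratio") %>%
    arrange(.data$residue_number, .data$ratio)
  res_ids <- sort(unique(wide$residue_number))
  # residues observed at every point, with the reference first
  keep <- vapply(res_ids, function(r) {
    sum(wide$residue_number == r) == length(ratios)
  }, logical(1))
  res_ids <- res_ids[keep]
  if (length(res_ids) == 0L) abort("no residue is observed at every titration point")

  get_mat <- function(col) {
    vapply(res_ids, function(r) {
      sub <- wide[wide$residue_number == r, ]
      sub[[col]][match(ratios, sub$ratio)]
    }, numeric(length(ratios)))
  }
  h_mat <- get_mat("dH_ppm")   # points x residues
  n_mat <- get_mat("dN_ppm")
  dh <- sweep(h_mat, 2, h_mat[1, ])          # shift change from reference
  dn <- sweep(n_mat, 2, n_mat[1, ]) * n_weight

  total_change <- max(abs(dh), abs(dn))
  if (total_change < 1e-6) {
    abort("no shift change across the titration; Kd is unidentifiable (flat residual surface)")
  }

  rss_for_kd <- function(log_kd, dh, dn) {
    fb <- fraction_bound(P_total_uM, l_tot, exp(log_kd))
    ss_fb <- sum(fb^2)
    if (ss_fb == 0) return(sum(dh^2) + sum(dn^2))
    # endpoints enter linearly: profile them out per residue and dimension
    bh <- colSums(dh * fb) / ss_fb
    bn <- colSums(dn * fb) / ss_fb
    sum((dh - outer(fb, bh))^2) + sum((dn - outer(fb, bn))^2)
  }

  fit_one <- function(dh, dn) {
    opt <- optimize(rss_for_kd, interval = log(c(1e-3, 1e6)), dh = dh, dn = dn)
    kd <- exp(opt$minimum)
    rss <- opt$objective
    # standard error from the curvature of the profile RSS in Kd
    eps <- 1e-3
    f0 <- rss
    fp <- rss_for_kd(opt$minimum + eps, dh, dn)
    fm <- rss_for_kd(opt$minimum - eps, dh, dn)
    d2 <- (fp - 2 * f0 + fm) / eps^2   # in log Kd
    ndof <- max(1L, 2L * length(dh) - 2L * ncol(dh) - 1L)
    sigma2 <- rss / ndof
    se_log <- if (d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
    list(kd = kd, kd_se = kd * se_log, rss = rss)
  }

  fb_tab <- function(kd) {
    tibble(ratio = ratios, L_total_uM = l_tot,
           fraction_bound = fraction_bound(P_total_uM, l_tot, kd))
  }
  endpoints <- function(kd) {
    fb <- fraction_bound(P_total_uM, l_tot, kd)
    ss <- sum(fb^2)
    tibble(
      residue_number = res_ids,
      delta_dH_bound = colSums(dh * fb) / ss,
      delta_dN_bound = colSums(dn * fb) / ss / n_weight
    )
  }

  if (mode == "global") {
    g <- fit_one(dh, dn)
    out <- list(
      Kd_uM = g$kd, Kd_se_uM = g$kd_se, mode = mode,
      P_total_uM = P_total_uM,
      endpoints = endpoints(g$kd),
      fraction_bound = fb_tab(g$kd),
      residual_norm = sqrt(g$rss),
      n_points = length(ratios), n_residues = length(res_ids),
      per_residue = NULL
    )
  } else {
    per <- purrr::map_dfr(seq_along(res_ids), function(j) {
      f <- fit_one(dh[, j, drop = FALSE], dn[, j, drop = FALSE])
      tibble(residue_number = res_ids[j], Kd_uM = f$kd,
             Kd_se_uM = f$kd_se, residual_norm = sqrt(f$rss))
    })
    med <- stats::median(per$Kd_uM)
    out <- list(
      Kd_uM = med, Kd_se_uM = stats::mad(per$Kd_uM), mode = mode,
      P_total_uM = P_total_uM,
      endpoints = endpoints(med),
      fraction_bound = fb_tab(med),
      residual_norm = sqrt(sum(per$residual_norm^2)),
      n_points = length(ratios), n_residues = length(res_ids),
      per_residue = per
    )
  }
  class(out) <- "binding_curve_fit"
  out
}

#' @export
print.binding_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<binding_curve_fit> Kd = %.2f uM (se %.2f), %s mode, %d residues x %d points\n",
    x$Kd_uM, x$Kd_se_uM, x$mode, x$n_residues, x$n_points
  ))
  invisible(x)
}

#' Per-point intensity ratios across a titration
#'
#' `I_point / I_reference` per residue, a proxy for exchange broadening;
#' in intermediate exchange the ratio dips at intermediate saturation
#' (where `pf pb` peaks) and partially recovers towards the endpoint.
#'
#' @param series Titration tibble with `residue_number`, `intensity`,
#'   `ratio` (reference at `ratio == 0`).
#' @return Tibble: `residue_number`, `ratio`, `intensity_ratio`,
#'   `reference_zero` (TRUE when the reference intensity was zero and the
#'   ratio is undefined).
#' @export
intensity_attenuation <- function(series) {
  if (!0 %in% series$ratio) abort("reference point (ratio 0) is required")
  ref <- series[series$ratio == 0, c("residue_number", "intensity")]
  names(ref)[2] <- "I_ref"
  out <- series %>%
    left_join(ref, by = "residue_number") %>%
    mutate(
      reference_zero = !is.na(.data$I_ref) & .data$I_ref == 0,
      intensity_ratio = ifelse(.data$reference_zero | is.na(.data$I_ref),
                               NA_real_, .data$intensity / .data$I_ref)
    ) %>%
    select("residue_number", "ratio", "intensity_ratio", "reference_zero")
  out
}

#' Map a CSP profile onto a structure via the B-factor column
#'
#' Writes the structure with per-residue `csp_avg * scale` in the B-factor
#' column (clipped to the PDB field range by [write_pdb()]), ready for
#' colouring in a molecular viewer.
#'
#' @param profile A `csp_profile` tibble.
#' @param structure A structure tibble.
#' @param out_path Output PDB path.
#' @param scale Multiplier applied to `csp_avg` before writing
#'   (default 100, so 0.0608 ppm becomes B = 6.08).
#' @return `out_path`, invisibly.
#' @export
map_to_structure <- function(profile, structure, out_path, scale = 100) {
  prof <- profile[profile$matched & !is.na(profile$csp_avg), ]
  struct_res <- unique(structure$residue_number)
  if (length(intersect(prof$residue_number, struct_res)) == 0L) {
    abort("profile and structure share no residues")
  }
  gaps <- setdiff(prof$residue_number, struct_res)
  if (length(gaps) > 0L) {
    warn(sprintf("structure is missing profile residue(s): %s",
                 paste(gaps, collapse = ", ")))
  }
  vals <- setNames(prof$csp_avg * scale, prof$residue_number)
  write_pdb(structure, out_path, bfactor_values = vals)
  invisible(out_path)
}
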