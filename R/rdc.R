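# Residual dipolar coupling analysis: amide bond-vector extraction,
# SVD fitting of the five-element Saupe (alignment) tensor directly in
# coupling units, tensor parameterisation (Da, rhombicity, ZYZ Euler
# angles), R-factor, and the per-domain versus joint fit comparison used
# as a test of interdomain rigidity.

#' Construct an alignment tensor from its principal parameters
#'
#' The tensor is traceless and symmetric; its principal values are
#' `Azz = 2 Da`, `Axx = -Da (1 - 1.5 R)`, `Ayy = -Da (1 + 1.5 R)`, rotated
#' into the molecular frame by ZYZ Euler angles.
#'
#' @param Da Tensor magnitude, Hz (half the largest-magnitude principal
#'   value; couplings are fitted directly in Hz so the dipolar prefactor is
#'   absorbed into the tensor).
#' @param rhombicity Rhombicity R in `[0, 2/3]`.
#' @param euler_deg ZYZ Euler angles (phi, theta, psi) in degrees rotating
#'   the principal frame into the molecular frame.
#' @return An `alignment_tensor` object (list with `saupe` 3x3 matrix,
#'   `Da`, `rhombicity`, `euler_deg`).
#' @export
#' @examples
#' alignment_tensor(10.6, 0.23)
alignment_tensor <- function(Da, rhombicity = 0, euler_deg = c(0, 0, 0)) {
  if (rhombicity < 0 || rhombicity > 2 / 3) {
    abort("rhombicity must lie in [0, 2/3]")
  }
  azz <- 2 * Da
  axx <- -Da * (1 - 1.5 * rhombicity)
  ayy <- -Da * (1 + 1.5 * rhombicity)
  rot <- euler_zyz_matrix(euler_deg)
  saupe <- rot %*% diag(c(axx, ayy, azz)) %*% t(rot)
  new_alignment_tensor(saupe)
}

new_alignment_tensor <- function(saupe) {
  saupe <- (saupe + t(saupe)) / 2
  saupe <- saupe - diag(3) * sum(diag(saupe)) / 3  # enforce tracelessness
  p <- tensor_params(saupe)
  structure(
    list(saupe = saupe, Da = p$Da, rhombicity = p$rhombicity,
         euler_deg = p$euler_deg),
    class = "alignment_tensor"
  )
}

#' @export
print.alignment_tensor <- function(x, ...) {
  cat(sprintf(
    "<alignment_tensor> Da = %.3f Hz, R = %.3f, Euler ZYZ = (%.1f, %.1f, %.1f) deg\n",
    x$Da, x$rhombicity, x$euler_deg[1], x$euler_deg[2], x$euler_deg[3]
  ))
  invisible(x)
}

euler_zyz_matrix <- function(euler_deg) {
  e <- euler_deg * pi / 180
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                           3, 3, byrow = TRUE)
  rz(e[1]) %*% ry(e[2]) %*% rz(e[3])
}

euler_from_matrix <- function(rot) {
  theta <- acos(min(1, max(-1, rot[3, 3])))
  if (abs(sin(theta)) < 1e-12) {
    phi <- atan2(rot[2, 1], rot[1, 1])
    psi <- 0
  } else {
    phi <- atan2(rot[2, 3], rot[1, 3])
    psi <- atan2(rot[3, 2], -rot[3, 1])
  }
  (c(phi, theta, psi) * 180 / pi) %% 360
}

#' Principal parameters of a Saupe matrix
#'
#' Eigendecomposes a traceless symmetric 3x3 order tensor, orders the
#' principal values by magnitude (`|Azz| >= |Ayy| >= |Axx|`), and returns
#' `Da = Azz/2`, rhombicity `R = (Axx - Ayy)/(3 Da)` in `[0, 2/3]`, and ZYZ
#' Euler angles in degrees, canonicalised to the sign-degenerate frame with
#' `theta` in `[0, 90]`.
#'
#' @param saupe A 3x3 symmetric traceless matrix, or an `alignment_tensor`.
#' @return A list with `Da`, `rhombicity`, `euler_deg`, `principal_values`
#'   (Axx, Ayy, Azz) and a `degenerate` flag set when Axx and Ayy are
#'   numerically indistinguishable.
#' @export
tensor_params <- function(saupe) {
  if (inherits(saupe, "alignment_tensor")) saupe <- saupe$saupe
  ev <- eigen(saupe, symmetric = TRUE)
  ord <- order(abs(ev$values))  # ascending: Axx, Ayy, Azz
  vals <- ev$values[ord]
  vecs <- ev$vectors[, ord, drop = FALSE]
  axx <- vals[1]; ayy <- vals[2]; azz <- vals[3]
  da <- azz / 2
  degenerate <- FALSE
  if (abs(da) < 1e-300) {
    abort("zero tensor has no principal parameters")
  }
  r <- (axx - ayy) / (3 * da)
  if (abs(ayy - axx) < 1e-9 * max(1, abs(azz))) {
    r <- if (abs(r) > 1 / 3) 2 / 3 else 0
    degenerate <- TRUE
  }
  r <- min(max(r, 0), 2 / 3)
  # right-handed frame, then pick the sign-degenerate representative with
  # theta in [0, 90]
  if (det(vecs) < 0) vecs[, 1] <- -vecs[, 1]
  flips <- list(c(1, 1), c(-1, 1), c(1, -1), c(-1, -1))
  best <- NULL
  for (fl in flips) {
    v <- vecs
    v[, 1] <- v[, 1] * fl[1]
    v[, 3] <- v[, 3] * fl[2]
    v[, 2] <- vcross(v[, 3], v[, 1])  # y = z x x keeps the frame right-handed
    ang <- euler_from_matrix(v)
    if (ang[2] <= 90 + 1e-9 && (is.null(best) || ang[2] < best[2])) best <- ang
  }
  list(Da = da, rhombicity = r, euler_deg = best,
       principal_values = c(Axx = axx, Ayy = ayy, Azz = azz),
       degenerate = degenerate)
}

#' Amide N-H unit bond vectors from a structure
#'
#' @param structure A structure tibble with N (and H) atoms.
#' @param residues Optional residue numbers to restrict to; defaults to all
#'   residues having an N atom. Prolines (no amide H) are skipped with a
#'   message.
#' @param build_h Build missing amide H atoms from C'(i-1), N, CA geometry
#'   (1.02 Angstrom, in the peptide plane) instead of erroring.
#' @return A tibble with `residue_number`, `vx`, `vy`, `vz` (unit vectors
#'   pointing N to H).
#' @export
nh_unit_vectors <- function(structure, residues = NULL, build_h = FALSE) {
  atoms <- structure
  get_atom <- function(res, name) {
    row <- atoms[atoms$residue_number == res & atoms$atom_name == name, ]
    if (nrow(row) == 0L) return(NULL)
    c(row$x[1], row$y[1], row$z[1])
  }
  all_res <- sort(unique(atoms$residue_number[atoms$atom_name == "N"]))
  if (is.null(residues)) residues <- all_res
  pro <- unique(atoms$residue_number[atoms$residue_name %in% c("PRO", "P")])
  skipped <- intersect(residues, pro)
  if (length(skipped) > 0L) {
    inform(sprintf("skipping proline residue(s): %s",
                   paste(skipped, collapse = ", ")))
    residues <- setdiff(residues, pro)
  }
  out <- list()
  missing_h <- integer(0)
  for (res in residues) {
    n <- get_atom(res, "N")
    if (is.null(n)) next
    h <- get_atom(res, "H")
    if (is.null(h)) {
      if (build_h) {
        cprev <- get_atom(res - 1L, "C")
        ca <- get_atom(res, "CA")
        if (is.null(cprev) || is.null(ca)) {
          inform(sprintf("residue %d: cannot build H (chain terminus); skipped", res))
          next
        }
        h <- place_amide_h(cprev, n, ca)
      } else {
        missing_h <- c(missing_h, res)
        next
      }
    }
    v <- vunit(h - n)
    out[[length(out) + 1L]] <- tibble(residue_number = as.integer(res),
                                      vx = v[1], vy = v[2], vz = v[3])
  }
  if (length(missing_h) > 0L) {
    abort(sprintf(
      "amide H missing for residue(s) %s; rerun with build_h = TRUE or supply H coordinates",
      paste(missing_h, collapse = ", ")
    ))
  }
  if (length(out) == 0L) abort("no N-H vectors could be extracted")
  bind_rows(out)
}

#' Back-calculate RDCs from a tensor and bond vectors
#'
#' `D_calc = v' A v` for each unit vector, with `A` the reconstructed 3x3
#' Saupe matrix in coupling units.
#'
#' @param tensor An `alignment_tensor` (or bare 3x3 Saupe matrix).
#' @param vectors Tibble from [nh_unit_vectors()].
#' @return `vectors` with a `D_calc_Hz` column added.
#' @export
back_calc_rdc <- function(tensor, vectors) {
  a <- if (inherits(tensor, "alignment_tensor")) tensor$saupe else tensor
  v <- as.matrix(vectors[, c("vx", "vy", "vz")])
  vectors$D_calc_Hz <- rowSums((v %*% a) * v)
  vectors
}

#' RDC quality factor
#'
#' `R = 100 sqrt(mean((D_obs - D_calc)^2) / (2 mean(D_obs^2)))`, in percent.
#'
#' @param d_obs,d_calc Observed and back-calculated couplings, Hz.
#' @return The R-factor in percent.
#' @export
#' @examples
#' r_factor(c(2, -2), c(1, -1))  # 35.36
r_factor <- function(d_obs, d_calc) {
  stopifnot(length(d_obs) == length(d_calc), length(d_obs) >= 1L)
  denom <- 2 * mean(d_obs^2)
  if (denom == 0) abort("all observed couplings are zero; R-factor undefined")
  100 * sqrt(mean((d_obs - d_calc)^2) / denom)
}

rdc_design_matrix <- function(vectors) {
  cx <- vectors$vx; cy <- vectors$vy; cz <- vectors$vz
  cbind(cy^2 - cx^2, cz^2 - cx^2, 2 * cx * cy, 2 * cx * cz, 2 * cy * cz)
}

saupe_from_elements <- function(p) {
  # p = (Ayy, Azz, Axy, Axz, Ayz); Axx from tracelessness
  matrix(c(-p[1] - p[2], p[3], p[4],
           p[3], p[1], p[5],
           p[4], p[5], p[2]), 3, 3, byrow = TRUE)
}

#' Fit an alignment tensor to observed RDCs by SVD
#'
#' Linear least squares for the five independent Saupe elements against the
#' observed couplings, solved through the singular value decomposition of
#' the design matrix (rows built from the N-H direction cosines). Couplings
#' are fitted directly in Hz; the dipolar prefactor is absorbed into the
#' tensor, so `Da` comes out in Hz as usually tabulated.
#'
#' @param rdcs Tibble with `residue_number`, `D_obs_Hz` and optionally
#'   `D_err_Hz` (see [read_rdc_table()]).
#' @param vectors Tibble from [nh_unit_vectors()].
#' @param weighted Weight rows by `1/D_err^2` when errors are supplied
#'   (default `FALSE`: unweighted).
#' @return An `rdc_fit` object: `tensor` (`alignment_tensor`), `data`
#'   (per-residue `D_obs_Hz`, `D_calc_Hz`, `residual_Hz`), `r_factor` (%),
#'   `rmsd` (Hz), `n_rdcs`, `condition_number`.
#' @export
svd_fit_tensor <- function(rdcs, vectors, weighted = FALSE) {
  dat <- inner_join(rdcs, vectors, by = "residue_number")
  if (nrow(dat) < 5L) {
    abort(sprintf("need >= 5 matched RDC/vector pairs; got %d", nrow(dat)))
  }
  amat <- rdc_design_matrix(dat)
  b <- dat$D_obs_Hz
  w <- NULL
  if (weighted && "D_err_Hz" %in% names(dat) && all(!is.na(dat$D_err_Hz))) {
    w <- 1 / dat$D_err_Hz^2
    sw <- sqrt(w)
    amat_fit <- amat * sw
    b_fit <- b * sw
  } else {
    amat_fit <- amat
    b_fit <- b
  }
  sv <- svd(amat_fit)
  if (sv$d[1] <= 0 || sv$d[5] / sv$d[1] < 1e-10) {
    abort(sprintf(
      "design matrix is rank deficient (condition number %.3g); bond vectors are too collinear to determine a tensor",
      if (sv$d[5] > 0) sv$d[1] / sv$d[5] else Inf
    ))
  }
  cond <- sv$d[1] / sv$d[5]
  if (cond > 100) {
    warn(sprintf("ill-conditioned tensor fit (condition number %.1f)", cond))
  }
  p <- as.numeric(sv$v %*% (crossprod(sv$u, b_fit) / sv$d))
  tensor <- new_alignment_tensor(saupe_from_elements(p))
  d_calc <- as.numeric(amat %*% p)
  res <- b - d_calc
  out <- list(
    tensor = tensor,
    data = tibble(residue_number = dat$residue_number,
                  D_obs_Hz = b, D_calc_Hz = d_calc, residual_Hz = res),
    r_factor = r_factor(b, d_calc),
    rmsd = sqrt(mean(res^2)),
    n_rdcs = nrow(dat),
    condition_number = cond
  )
  class(out) <- "rdc_fit"
  out
}

#' @export
print.rdc_fit <- function(x, ...) {
  cat(sprintf(
    "<rdc_fit> n = %d, Da = %.2f Hz, R = %.2f, R-factor = %.2f%%, rmsd = %.3f Hz\n",
    x$n_rdcs, x$tensor$Da, x$tensor$rhombicity, x$r_factor, x$rmsd
  ))
  invisible(x)
}

parse_domain_spec <- function(domain_defs) {
  if (is.character(domain_defs)) {
    parts <- strsplit(domain_defs, ",", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^\\s*(\\d+)-(\\d+):(.+)$", parts))
    bad <- vapply(m, length, integer(1)) != 4L
    if (any(bad)) {
      abort("domain spec must look like '1-93:RRM1,94-189:RRM2'")
    }
    return(tibble(
      start = vapply(m, function(g) as.integer(g[2]), integer(1)),
      end = vapply(m, function(g) as.integer(g[3]), integer(1)),
      label = vapply(m, function(g) trimws(g[4]), character(1))
    ))
  }
  as_tibble(domain_defs)
}

#' Per-domain versus joint alignment-tensor fits
#'
#' Fits one tensor per domain and a single joint tensor over all residues,
#' then compares. A rigid multidomain protein aligns as one body, so the
#' joint fit should do as well as the per-domain fits; a large degradation
#' of the joint R-factor relative to the per-domain fits indicates that the
#' domains do not share an alignment frame, i.e. they reorient
#' independently in solution.
#'
#' @param rdcs RDC tibble (`residue_number`, `D_obs_Hz`, ...).
#' @param structure Structure tibble supplying N-H vectors.
#' @param domain_defs Domain definition: tibble with `start`, `end`,
#'   `label`, or a string like `"1-93:RRM1,94-189:RRM2"`; defaults to the
#'   structure's own domain annotation.
#' @param mode `"both"` (default), `"separate"` or `"joint"`.
#' @param build_h Passed to [nh_unit_vectors()].
#' @return An `rdc_domain_comparison`: `fits` (named list of `rdc_fit`),
#'   `summary` tibble (one row per domain plus `"joint"`: n, Da,
#'   rhombicity, R-factor), `percent_increase` of the joint R-factor over
#'   the RDC-count-weighted mean of the per-domain R-factors, and
#'   `tensor_difference` between the first two domain tensors.
#' @export
fit_domains <- function(rdcs, structure, domain_defs = NULL,
                        mode = c("both", "separate", "joint"),
                        build_h = FALSE) {
  mode <- match.arg(mode)
  if (is.null(domain_defs)) domain_defs <- structure_domains(structure)
  if (is.null(domain_defs)) {
    abort("no domain definitions: supply domain_defs or a structure with domains")
  }
  dom <- parse_domain_spec(domain_defs)
  vectors <- nh_unit_vectors(structure, build_h = build_h)
  fits <- list()
  rows <- list()
  if (mode %in% c("both", "separate")) {
    for (i in seq_len(nrow(dom))) {
      lab <- dom$label[i]
      sel <- rdcs$residue_number >= dom$start[i] & rdcs$residue_number <= dom$end[i]
      if (sum(sel & rdcs$residue_number %in% vectors$residue_number) < 5L) {
        abort(sprintf("domain '%s' has fewer than 5 usable RDCs", lab))
      }
      fit <- svd_fit_tensor(rdcs[sel, ], vectors)
      fits[[lab]] <- fit
      rows[[lab]] <- tibble(domain = lab, n_rdcs = fit$n_rdcs,
                            Da_Hz = fit$tensor$Da,
                            rhombicity = fit$tensor$rhombicity,
                            r_factor = fit$r_factor)
    }
  }
  if (mode %in% c("both", "joint")) {
    fit <- svd_fit_tensor(rdcs, vectors)
    fits[["joint"]] <- fit
    rows[["joint"]] <- tibble(domain = "joint", n_rdcs = fit$n_rdcs,
                              Da_Hz = fit$tensor$Da,
                              rhombicity = fit$tensor$rhombicity,
                              r_factor = fit$r_factor)
  }
  summary <- bind_rows(rows)
  percent_increase <- NA_real_
  tensor_diff <- NULL
  sep <- summary[summary$domain != "joint", ]
  if (mode == "both" && nrow(sep) >= 1L) {
    wmean <- sum(sep$r_factor * sep$n_rdcs) / sum(sep$n_rdcs)
    percent_increase <- 100 * (fits[["joint"]]$r_factor - wmean) / wmean
    if (nrow(sep) >= 2L) {
      tensor_diff <- tensor_difference(fits[[sep$domain[1]]]$tensor,
                                       fits[[sep$domain[2]]]$tensor)
    }
  }
  structure(
    list(fits = fits, summary = summary, percent_increase = percent_increase,
         tensor_difference = tensor_diff, mode = mode),
    class = "rdc_domain_comparison"
  )
}

#' @export
print.rdc_domain_comparison <- function(x, ...) {
  cat("<rdc_domain_comparison>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  if (!is.na(x$percent_increase)) {
    cat(sprintf("joint R-factor exceeds weighted per-domain mean by %.1f%%\n",
                x$percent_increase))
  }
  invisible(x)
}

#' Compare two alignment tensors
#'
#' The normalized generalized scalar product (Frobenius inner product of
#' the two Saupe matrices over the product of their norms) is 1 for
#' identical orientation and shape up to scale; differing principal frames
#' drive it below 1 (and negative for strongly rotated frames).
#'
#' @param tensor_a,tensor_b `alignment_tensor` objects.
#' @return A list: `scalar_product` in `[-1, 1]`, `delta_Da_Hz`,
#'   `delta_rhombicity`, `rotation_deg` (angle between principal z axes).
#' @export
tensor_difference <- function(tensor_a, tensor_b) {
  a <- tensor_a$saupe; b <- tensor_b$saupe
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("cannot compare a zero tensor")
  sp <- sum(a * b) / (na * nb)
  zaxis <- function(s) {
    ev <- eigen(s, symmetric = TRUE)
    ev$vectors[, which.max(abs(ev$values))]
  }
  za <- zaxis(a); zb <- zaxis(b)
  ang <- acos(min(1, abs(sum(za * zb)))) * 180 / pi
  list(
    scalar_product = sp,
    delta_Da_Hz = tensor_b$Da - tensor_a$Da,
    delta_rhombicity = tensor_b$rhombicity - tensor_a$rhombicity,
    rotation_deg = ang
  )
}
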