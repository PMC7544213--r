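# Toy-structure generator: ideal backbone geometry built by internal
# coordinates (NeRF placement), used as the no-download stand-in for a
# crystal structure when exercising the RDC and CSP mapping stages.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
vunit <- function(v) v / sqrt(sum(v^2))

# place atom D from A-B-C with bond length r (C-D), bond angle theta (B-C-D,
# degrees) and dihedral phi (A-B-C-D, degrees)
place_atom <- function(a, b, c_, r, theta, phi) {
  theta <- theta * pi / 180
  phi <- phi * pi / 180
  d2 <- r * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  bc <- vunit(c_ - b)
  n <- vunit(vcross(b - a, bc))
  m <- cbind(bc, vcross(n, bc), n)
  as.numeric(m %*% d2 + c_)
}

# standard backbone covalent geometry (Angstrom, degrees)
bb_geom <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231, b_NH = 1.02,
  a_CNCA = 121.7, a_NCAC = 111.2, a_CACN = 116.2, a_CACO = 120.8
)

# amide H: in the C'(i-1)-N-CA plane, anti to the bisector, 1.02 A from N
place_amide_h <- function(c_prev, n, ca) {
  u <- vunit(c_prev - n) + vunit(ca - n)
  as.numeric(n - bb_geom$b_NH * vunit(u))
}

# build one chain of n residues at fixed (phi, psi); returns a list of
# per-residue atom coordinate lists
build_chain <- function(n_residues, phi, psi, omega = 180) {
  g <- bb_geom
  # seed with a virtual residue so residue 1 has a preceding C' for its
  # amide H and a defined phi
  n0 <- c(0, 0, 0)
  ca0 <- c(g$b_NCA, 0, 0)
  c0 <- place_atom(c(0, 1, 0), n0, ca0, g$b_CAC, g$a_NCAC, 60)
  res <- vector("list", n_residues)
  prev <- list(N = n0, CA = ca0, C = c0)
  for (i in seq_len(n_residues)) {
    N <- place_atom(prev$N, prev$CA, prev$C, g$b_CN, g$a_CACN, psi)
    CA <- place_atom(prev$CA, prev$C, N, g$b_NCA, g$a_CNCA, omega)
    C <- place_atom(prev$C, N, CA, g$b_CAC, g$a_NCAC, phi)
    O <- place_atom(N, CA, C, g$b_CO, g$a_CACO, psi + 180)
    H <- place_amide_h(prev$C, N, CA)
    res[[i]] <- list(N = N, H = H, CA = CA, C = C, O = O)
    prev <- list(N = N, CA = CA, C = C)
  }
  res
}

chain_to_tibble <- function(res, first_residue = 1L) {
  rows <- purrr::imap(res, function(atoms, i) {
    tibble(
      residue_number = first_residue + i - 1L,
      residue_name = "ALA",
      atom_name = names(atoms),
      x = vapply(atoms, `[`, numeric(1), 1),
      y = vapply(atoms, `[`, numeric(1), 2),
      z = vapply(atoms, `[`, numeric(1), 3)
    )
  })
  bind_rows(rows)
}

rotation_matrix <- function(axis, angle_deg) {
  u <- vunit(axis)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), 3, 3, byrow = TRUE)
}

transform_coords <- function(structure, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(structure[, c("x", "y", "z")]) %*% t(rot)
  structure$x <- xyz[, 1] + shift[1]
  structure$y <- xyz[, 2] + shift[2]
  structure$z <- xyz[, 3] + shift[3]
  structure
}

#' Generate an idealised backbone structure
#'
#' Builds N, H, CA, C, O backbone atoms with ideal covalent geometry at
#' fixed backbone dihedrals: an alpha-helix (phi = -57, psi = -47), an
#' extended strand (phi = -135, psi = 135), or two helical domains related
#' by an exact, recorded rotation and translation. The amide H is placed
#' 1.02 Angstrom from N in the peptide plane, anti to the
#' C'(i-1)-N-CA bisector. Generation is fully deterministic.
#'
#' @param n_residues Residues per chain (per domain for `"two_domain"`);
#'   at least 5 (fewer cannot support a five-parameter tensor fit
#'   downstream).
#' @param geometry `"helix"`, `"strand"` or `"two_domain"`.
#' @param rotation_deg Inter-domain rotation (about the z axis) for
#'   `"two_domain"`; recorded in the `interdomain_rotation_deg` attribute.
#' @param translation_A Inter-domain translation along x, in Angstrom.
#' @param seed Accepted for interface symmetry with the stochastic
#'   generators; the geometry is deterministic.
#' @return A structure tibble; for `"two_domain"`, domain labels `"D1"`,
#'   `"D2"` are attached (see [structure_domains()]).
#' @export
#' @examples
#' s <- gen_structure(20, "helix")
#' dplyr::count(s, atom_name)
gen_structure <- function(n_residues, geometry = c("helix", "strand", "two_domain"),
                          rotation_deg = 90, translation_A = 30, seed = NULL) {
  geometry <- match.arg(geometry)
  if (n_residues < 5) {
    abort("n_residues must be >= 5 per domain (tensor fitting needs >= 5 vectors)")
  }
  if (geometry == "helix") {
    out <- chain_to_tibble(build_chain(n_residues, phi = -57, psi = -47))
    out <- structure_tibble(out$residue_number, out$residue_name, out$atom_name,
                            out$x, out$y, out$z)
  } else if (geometry == "strand") {
    out <- chain_to_tibble(build_chain(n_residues, phi = -135, psi = 135))
    out <- structure_tibble(out$residue_number, out$residue_name, out$atom_name,
                            out$x, out$y, out$z)
  } else {
    d1 <- chain_to_tibble(build_chain(n_residues, phi = -57, psi = -47))
    d2 <- chain_to_tibble(build_chain(n_residues, phi = -57, psi = -47),
                          first_residue = n_residues + 1L)
    d2 <- transform_coords(d2, rot = rotation_matrix(c(0, 0, 1), rotation_deg),
                           shift = c(translation_A, 0, 0))
    out <- bind_rows(d1, d2)
    out <- structure_tibble(out$residue_number, out$residue_name, out$atom_name,
                            out$x, out$y, out$z)
    out <- set_structure_domains(out, tibble(
      start = c(1L, n_residues + 1L),
      end = c(n_residues, 2L * n_residues),
      label = c("D1", "D2")
    ))
    attr(out, "interdomain_rotation_deg") <- rotation_deg
    attr(out, "interdomain_translation_A") <- translation_A
  }
  out
}
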