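# Shared fixtures, generated in code at test time.

# evenly spread synthetic amide peaks in typical HSQC windows
make_peaklist <- function(n = 10, seed = 42) {
  withr::with_seed(seed, tibble::tibble(
    residue_number = seq_len(n),
    residue_name = sample(c("ALA", "GLY", "LEU", "SER"), n, replace = TRUE),
    dH_ppm = round(stats::runif(n, 7, 9.5), 3),
    dN_ppm = round(stats::runif(n, 105, 130), 3),
    intensity = round(stats::runif(n, 5e5, 2e6))
  ))
}

write_peaklist_file <- function(pk, path = tempfile(fileext = ".tsv")) {
  nmrbind::write_peaklist(pk, path)
  path
}

# bound-state endpoints with 1H changes >= 0.05 ppm so Kd is identifiable
make_endpoints <- function(residues, seed = 7) {
  withr::with_seed(seed, tibble::tibble(
    residue_number = residues,
    ddH_bound_ppm = sample(c(-1, 1), length(residues), TRUE) *
      stats::runif(length(residues), 0.05, 0.2),
    ddN_bound_ppm = stats::runif(length(residues), -1.5, 1.5)
  ))
}

random_unit_vectors <- function(n, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(3 * n), ncol = 3)
    m <- m / sqrt(rowSums(m^2))
    tibble::tibble(residue_number = seq_len(n),
                   vx = m[, 1], vy = m[, 2], vz = m[, 3])
  })
}

random_tensor <- function(seed) {
  withr::with_seed(seed, nmrbind::alignment_tensor(
    Da = stats::runif(1, 5, 15),
    rhombicity = stats::runif(1, 0.05, 0.6),
    euler_deg = stats::runif(3, 0, 180)
  ))
}
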