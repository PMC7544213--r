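test_that("combined CSP matches hand-evaluated worked examples", {
  # sqrt((0.05^2 + (0.14*0.5)^2)/2) = 0.06083
  expect_equal(csp_avg(0.05, 0.5), 0.0608, tolerance = 1e-3)
  # dH = 0, dN = 1: 0.14/sqrt(2)
  expect_equal(csp_avg(0, 1.0), 0.14 / sqrt(2), tolerance = 1e-12)
  expect_equal(csp_avg(0, 0), 0)
})

test_that("per-residue CSP is symmetric in magnitude and zero for identical spectra", {
  a <- make_peaklist(12, seed = 1)
  b <- a
  b$dH_ppm <- b$dH_ppm + withr::with_seed(2, rnorm(12, 0, 0.05))
  b$dN_ppm <- b$dN_ppm + withr::with_seed(3, rnorm(12, 0, 0.4))
  ab <- csp_per_residue(a, b)
  ba <- csp_per_residue(b, a)
  expect_equal(ab$csp_avg, ba$csp_avg, tolerance = 1e-12)
  expect_equal(ab$delta_dH, -ba$delta_dH, tolerance = 1e-12)
  expect_true(all(csp_per_residue(a, a)$csp_avg == 0))
})

test_that("CSP obeys the triangle inequality over composed titration steps", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      a <- runif(2, -0.2, 0.2); b <- runif(2, -0.2, 0.2); c_ <- runif(2, -2, 2)
    })
    d_ac <- csp_avg(a[1] + b[1], c_[1] + c_[2])
    d_ab <- csp_avg(a[1], c_[1])
    d_bc <- csp_avg(b[1], c_[2])
    expect_lte(d_ac, d_ab + d_bc + 1e-12)
  }
})

test_that("residues in only one list are flagged, not dropped silently", {
  a <- make_peaklist(6)
  b <- a[-3, ]
  prof <- csp_per_residue(a, b)
  expect_false(prof$matched[prof$residue_number == 3])
  expect_true(is.na(prof$csp_avg[prof$residue_number == 3]))
})

test_that("large-shift classification is strictly greater than the threshold", {
  prof <- csp_per_residue(make_peaklist(3), make_peaklist(3))
  expect_length(classify_large(prof), 0L)
  prof$csp_avg <- c(0.025, 0.03, 0.01)
  prof$matched <- TRUE
  expect_equal(classify_large(prof), 2L)  # exactly 0.025 excluded
})

test_that("peak matching is identity for identical lists and respects the cutoff", {
  a <- make_peaklist(8)
  m <- match_peaks(a, a)
  expect_true(all(m$matched))
  expect_equal(m$other_residue, m$ref_residue)

  b <- a
  b$dH_ppm[4] <- b$dH_ppm[4] + 5  # move far beyond any cutoff
  m2 <- match_peaks(a, b, max_dist_ppm = 0.1)
  expect_false(m2$matched[m2$ref_residue == 4])
  expect_true(all(m2$matched[m2$ref_residue != 4]))
})

test_that("greedy matching minimizes summed distance for a swapped pair", {
  a <- tibble::tibble(residue_number = 1:2, residue_name = "ALA",
                      dH_ppm = c(8.00, 8.05), dN_ppm = c(120, 120),
                      intensity = 1)
  b <- a
  b$dH_ppm <- c(8.06, 8.01)  # nearest neighbours cross over
  m <- match_peaks(a, b, max_dist_ppm = 0.2)
  # brute force over both possible assignments
  d <- function(i, j) csp_avg(b$dH_ppm[j] - a$dH_ppm[i], 0)
  straight <- d(1, 1) + d(2, 2)
  crossed <- d(1, 2) + d(2, 1)
  best <- if (crossed < straight) c(2L, 1L) else c(1L, 2L)
  expect_equal(m$other_residue, best)
})

test_that("fraction bound solves the depletion quadratic exactly", {
  # P = L = Kd = 50: complex 19.10 uM, fb = 0.382
  expect_equal(50 * fraction_bound(50, 50, 50), 19.10, tolerance = 1e-3)
  expect_equal(fraction_bound(50, 0, 50), 0)
  expect_equal(fraction_bound(100, 200, 1e-9), 1, tolerance = 1e-6)
  expect_error(fraction_bound(0, 10, 50), "P = 0")
})

test_that("fraction bound matches the brute-force mass-balance root", {
  for (seed in 1:15) {
    withr::with_seed(seed, {
      p <- runif(1, 10, 500); l <- runif(1, 0, 1500); kd <- runif(1, 1, 300)
    })
    fb <- fraction_bound(p, l, kd)
    if (l == 0) next
    # independent numeric root of (P-PL)(L-PL)/PL = Kd
    pl <- uniroot(function(x) (p - x) * (l - x) - kd * x,
                  lower = 0, upper = min(p, l) * (1 - 1e-12),
                  tol = 1e-13)$root
    expect_equal(fb, pl / p, tolerance = 1e-10)
  }
})

test_that("fraction bound is monotone in ligand and in affinity", {
  l <- seq(0, 600, by = 30)
  fb <- fraction_bound(200, l, 52)
  expect_true(all(diff(fb) > 0))
  kds <- c(5, 20, 52, 150, 400)
  fbk <- vapply(kds, function(k) fraction_bound(200, 300, k), numeric(1))
  expect_true(all(diff(fbk) < 0))
})

test_that("global Kd fitting recovers the generating constant", {
  ref <- make_peaklist(10, seed = 5)
  ser <- gen_titration(ref, exchange_spec(52, make_endpoints(1:10)),
                       protein_conc_uM = 200)
  fit <- fit_kd_from_titration(ser, 200)
  expect_equal(fit$Kd_uM, 52, tolerance = 0.01)

  noisy <- gen_titration(ref, exchange_spec(52, make_endpoints(1:10)),
                         protein_conc_uM = 200, noise_sd = 0.002, seed = 9)
  fitn <- fit_kd_from_titration(noisy, 200)
  expect_equal(fitn$Kd_uM, 52, tolerance = 0.15)
  expect_true(is.finite(fitn$Kd_se_uM) && fitn$Kd_se_uM > 0)
})

test_that("per-residue fits bracket the global estimate", {
  ref <- make_peaklist(5, seed = 6)
  ser <- gen_titration(ref, exchange_spec(52, make_endpoints(1:5)),
                       protein_conc_uM = 200)
  g <- fit_kd_from_titration(ser, 200, mode = "global")
  p <- fit_kd_from_titration(ser, 200, mode = "per_residue")
  expect_equal(nrow(p$per_residue), 5L)
  expect_gte(g$Kd_uM, min(p$per_residue$Kd_uM) - 1e-6)
  expect_lte(g$Kd_uM, max(p$per_residue$Kd_uM) + 1e-6)
})

test_that("degenerate titrations are rejected with a clear message", {
  ref <- make_peaklist(4)
  flat <- gen_titration(ref, exchange_spec(
    52, tibble::tibble(residue_number = 1:4, ddH_bound_ppm = 0,
                       ddN_bound_ppm = 0)), protein_conc_uM = 200)
  expect_error(fit_kd_from_titration(flat, 200), "unidentifiable")
  two_pt <- gen_titration(ref, exchange_spec(52, make_endpoints(1:4)),
                          protein_conc_uM = 200, ligand_ratios = c(0, 1))
  expect_error(fit_kd_from_titration(two_pt, 200), "3 titration points")
})

test_that("intensity ratios are 1 without broadening and dip mid-titration with it", {
  ref <- make_peaklist(6, seed = 8)
  plain <- gen_titration(ref, exchange_spec(52, make_endpoints(1:6)),
                         protein_conc_uM = 200)
  att <- intensity_attenuation(plain)
  expect_true(all(abs(att$intensity_ratio - 1) < 1e-12))

  broad <- gen_titration(ref, exchange_spec(52, make_endpoints(1:6),
                                            kex_s = 1500, R2_0_s = 20),
                         protein_conc_uM = 200)
  attb <- intensity_attenuation(broad)
  by_res <- split(attb, attb$residue_number)
  for (d in by_res) {
    d <- d[order(d$ratio), ]
    expect_true(all(d$intensity_ratio[-1] < 1))
    # minimum lies at an intermediate point, not at either end:
    # Rex = pf*pb*dw^2/kex peaks where pf = pb
    k <- which.min(d$intensity_ratio)
    expect_gt(k, 1L)
    expect_lt(k, nrow(d))
  }
})

test_that("zero reference intensities are flagged rather than divided by", {
  ref <- make_peaklist(3)
  ref$intensity[2] <- 0
  ser <- gen_titration(ref, exchange_spec(52, make_endpoints(1:3)),
                       protein_conc_uM = 200)
  att <- intensity_attenuation(ser)
  expect_true(all(att$reference_zero[att$residue_number == 2]))
  expect_true(all(is.na(att$intensity_ratio[att$residue_number == 2])))
})

test_that("CSP maps onto the structure through the B-factor column", {
  s <- gen_structure(6, "helix")
  prof <- csp_per_residue(make_peaklist(6), make_peaklist(6))
  prof$csp_avg[2] <- 0.0608
  p <- tempfile(fileext = ".pdb")
  map_to_structure(prof, s, p)
  atom <- readLines(p)
  atom <- atom[startsWith(atom, "ATOM")]
  b2 <- as.numeric(substr(atom[as.integer(substr(atom, 23, 26)) == 2], 61, 66))
  expect_equal(unique(b2), 6.08)

  prof_bad <- prof
  prof_bad$residue_number <- prof_bad$residue_number + 100L
  expect_error(map_to_structure(prof_bad, s, tempfile()), "no residues")
  prof_gap <- prof
  prof_gap$residue_number[1] <- 99L
  expect_warning(map_to_structure(prof_gap, s, tempfile()), "99")
})
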