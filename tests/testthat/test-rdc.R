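test_that("N-H vectors are unit length and prolines are skipped", {
  s <- gen_structure(12, "helix")
  v <- nh_unit_vectors(s)
  expect_equal(sqrt(v$vx^2 + v$vy^2 + v$vz^2), rep(1, nrow(v)),
               tolerance = 1e-12)
  s_pro <- s
  s_pro$residue_name[s_pro$residue_number == 5] <- "PRO"
  expect_message(v2 <- nh_unit_vectors(s_pro), "proline")
  expect_false(5 %in% v2$residue_number)
})

test_that("built amide protons agree with exactly placed ones", {
  s <- gen_structure(10, "strand")
  exact <- nh_unit_vectors(s)
  s_noh <- s[s$atom_name != "H", ]
  expect_error(nh_unit_vectors(s_noh), "build_h")
  built <- suppressMessages(nh_unit_vectors(s_noh, build_h = TRUE))
  common <- intersect(exact$residue_number, built$residue_number)
  e <- as.matrix(exact[match(common, exact$residue_number), c("vx", "vy", "vz")])
  b <- as.matrix(built[match(common, built$residue_number), c("vx", "vy", "vz")])
  ang <- acos(pmin(1, rowSums(e * b)))
  expect_lt(max(ang), 1e-6)
})

test_that("noise-free SVD recovers arbitrary tensors to numerical precision", {
  for (seed in 1:8) {
    t0 <- random_tensor(seed)
    vec <- random_unit_vectors(40, seed = seed + 100)
    rdcs <- tibble::tibble(residue_number = vec$residue_number,
                           D_obs_Hz = back_calc_rdc(t0, vec)$D_calc_Hz)
    fit <- svd_fit_tensor(rdcs, vec)
    expect_lt(max(abs(fit$tensor$saupe - t0$saupe)), 1e-10)
    expect_lt(fit$r_factor, 1e-8)
    expect_equal(fit$tensor$Da, t0$Da, tolerance = 1e-9)
    expect_equal(fit$tensor$rhombicity, t0$rhombicity, tolerance = 1e-7)
  }
})

test_that("the fit demands five well-spread couplings", {
  vec <- random_unit_vectors(10)
  t0 <- alignment_tensor(10, 0.2)
  rdcs <- tibble::tibble(residue_number = 1:4,
                         D_obs_Hz = back_calc_rdc(t0, vec[1:4, ])$D_calc_Hz)
  expect_error(svd_fit_tensor(rdcs, vec[1:4, ]), ">= 5")
  par <- tibble::tibble(residue_number = 1:6, vx = 1, vy = 0, vz = 0)
  rdcs6 <- tibble::tibble(residue_number = 1:6, D_obs_Hz = rnorm(6))
  expect_error(svd_fit_tensor(rdcs6, par), "rank deficient|collinear")
})

test_that("tensor parameterisation handles axial, rhombic and reference cases", {
  ax <- alignment_tensor(10, 0)
  expect_equal(ax$rhombicity, 0)
  mx <- alignment_tensor(10, 2 / 3)
  expect_equal(mx$rhombicity, 2 / 3, tolerance = 1e-9)
  t2 <- alignment_tensor(9.2, 0.55, euler_deg = c(40, 60, 20))
  p <- tensor_params(t2$saupe)
  expect_equal(p$Da, 9.2, tolerance = 1e-9)
  expect_equal(p$rhombicity, 0.55, tolerance = 1e-9)
  expect_lte(p$euler_deg[2], 90)
  # reconstruction from recovered parameters reproduces the matrix
  t3 <- alignment_tensor(p$Da, p$rhombicity, p$euler_deg)
  expect_equal(t3$saupe, t2$saupe, tolerance = 1e-8)
  # trace is zero and principal values are magnitude-ordered
  expect_lt(abs(sum(diag(t2$saupe))), 1e-10)
  pv <- abs(p$principal_values)
  expect_true(pv["Azz"] >= pv["Ayy"] && pv["Ayy"] >= pv["Axx"])
})

test_that("back-calculation agrees between matrix and polar forms", {
  t0 <- alignment_tensor(8, 0.4)
  vec <- random_unit_vectors(100, seed = 12)
  mat_form <- back_calc_rdc(t0, vec)$D_calc_Hz
  # polar form in the principal frame: D = Da(3cos2th - 1 + 1.5 R sin2th cos2ph)
  polar <- apply(as.matrix(vec[, c("vx", "vy", "vz")]), 1, function(v) {
    ct <- v[3]; st2 <- v[1]^2 + v[2]^2
    ph <- atan2(v[2], v[1])
    8 * ((3 * ct^2 - 1) + 1.5 * 0.4 * st2 * cos(2 * ph))
  })
  expect_lt(max(abs(mat_form - polar)), 1e-10)
  # special directions
  zvec <- tibble::tibble(residue_number = 1L, vx = 0, vy = 0, vz = 1)
  expect_equal(back_calc_rdc(alignment_tensor(10, 0), zvec)$D_calc_Hz, 20)
  th <- acos(sqrt(1 / 3))  # magic angle
  mvec <- tibble::tibble(residue_number = 1L, vx = sin(th), vy = 0, vz = cos(th))
  expect_lt(abs(back_calc_rdc(alignment_tensor(10, 0), mvec)$D_calc_Hz), 1e-9)
})

test_that("the R-factor matches hand-evaluated values and rejects zero data", {
  expect_equal(r_factor(c(3, -1, 2), c(3, -1, 2)), 0)
  expect_equal(r_factor(c(2, -2), c(1, -1)), 35.36, tolerance = 1e-3)
  expect_equal(r_factor(c(2, -2), c(0, 0)), 100 / sqrt(2), tolerance = 1e-9)
  expect_error(r_factor(c(0, 0), c(1, 1)), "zero")
})

test_that("the R-factor is invariant under joint rotation of structure and tensor", {
  t0 <- alignment_tensor(10.6, 0.23, euler_deg = c(10, 40, 70))
  vec <- random_unit_vectors(30, seed = 3)
  rdcs <- tibble::tibble(residue_number = vec$residue_number,
                         D_obs_Hz = back_calc_rdc(t0, vec)$D_calc_Hz +
                           withr::with_seed(4, rnorm(30, 0, 1)))
  f1 <- svd_fit_tensor(rdcs, vec)
  rot <- nmrbind:::rotation_matrix(c(1, 2, 0.5), 73)
  m <- as.matrix(vec[, c("vx", "vy", "vz")]) %*% t(rot)
  vec_rot <- tibble::tibble(residue_number = vec$residue_number,
                            vx = m[, 1], vy = m[, 2], vz = m[, 3])
  f2 <- svd_fit_tensor(rdcs, vec_rot)
  expect_equal(f1$r_factor, f2$r_factor, tolerance = 1e-8)
})

test_that("the SVD solution is locally optimal against a parameter grid", {
  t0 <- random_tensor(21)
  vec <- random_unit_vectors(25, seed = 22)
  rdcs <- tibble::tibble(residue_number = vec$residue_number,
                         D_obs_Hz = back_calc_rdc(t0, vec)$D_calc_Hz +
                           withr::with_seed(23, rnorm(25, 0, 1.5)))
  fit <- svd_fit_tensor(rdcs, vec)
  s <- fit$tensor$saupe
  base <- c(s[2, 2], s[3, 3], s[1, 2], s[1, 3], s[2, 3])
  amat <- nmrbind:::rdc_design_matrix(vec)
  rss0 <- sum((rdcs$D_obs_Hz - amat %*% base)^2)
  grid <- expand.grid(rep(list(c(-0.2, 0, 0.2)), 5))
  rss <- apply(grid, 1, function(dp) {
    sum((rdcs$D_obs_Hz - amat %*% (base + as.numeric(dp)))^2)
  })
  expect_true(all(rss >= rss0 - 1e-9))
})

test_that("per-domain and joint fits expose shared vs distinct alignment", {
  s <- gen_structure(20, "two_domain", rotation_deg = 90)
  shared <- alignment_tensor(10.6, 0.23, euler_deg = c(15, 35, 55))
  rd_shared <- gen_rdc_set(s, shared)
  cmp0 <- fit_domains(rd_shared, s)
  expect_lt(max(cmp0$summary$r_factor), 1e-6)
  # a shared alignment frame with modest noise: joint fit holds up
  for (seed in 1:3) {
    rdn <- gen_rdc_set(s, shared, noise_sd = 0.5, seed = seed)
    expect_lt(abs(fit_domains(rdn, s)$percent_increase), 30)
  }

  tensors <- list(D1 = alignment_tensor(10.6, 0.23),
                  D2 = alignment_tensor(9.2, 0.55, euler_deg = c(0, 90, 0)))
  rd <- gen_rdc_set(s, tensors, noise_sd = 1, seed = 5)
  cmp <- fit_domains(rd, s)
  sep <- cmp$summary[cmp$summary$domain != "joint", ]
  joint <- cmp$summary[cmp$summary$domain == "joint", ]
  expect_gt(joint$r_factor, max(sep$r_factor))
  expect_gt(cmp$percent_increase, 50)

  only_sep <- fit_domains(rd, s, mode = "separate")
  expect_false("joint" %in% only_sep$summary$domain)
  expect_error(fit_domains(rd[rd$residue_number > 18, ], s), "fewer than 5")
})

test_that("domain specs parse from compact strings", {
  dom <- nmrbind:::parse_domain_spec("1-93:RRM1,94-189:RRM2")
  expect_equal(dom$start, c(1L, 94L))
  expect_equal(dom$label, c("RRM1", "RRM2"))
  expect_error(nmrbind:::parse_domain_spec("banana"), "1-93")
})

test_that("tensor comparison is scale-invariant and rotation-sensitive", {
  a <- alignment_tensor(10, 0.3, euler_deg = c(20, 40, 60))
  same <- tensor_difference(a, a)
  expect_equal(same$scalar_product, 1, tolerance = 1e-12)
  expect_equal(same$rotation_deg, 0, tolerance = 1e-6)
  scaled <- tensor_difference(a, new_tensor <- alignment_tensor(20, 0.3, c(20, 40, 60)))
  expect_equal(scaled$scalar_product, 1, tolerance = 1e-9)
  ax <- alignment_tensor(10, 0)
  rot90 <- alignment_tensor(10, 0, euler_deg = c(0, 90, 0))
  expect_lt(tensor_difference(ax, rot90)$scalar_product, 0)
  expect_equal(tensor_difference(ax, rot90)$rotation_deg, 90, tolerance = 1e-6)
})
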