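test_that("injection bookkeeping dilutes the cell and accumulates titrant", {
  sch <- injection_schedule(volumes_uL = c(10, 10), cell_volume_mL = 1.4,
                            syringe_conc_uM = 100, cell_conc_uM = 50)
  after1 <- concentrations_after_injection(sch, 1)
  expect_equal(after1$titrand_uM, 50 * (1 - 10 / 1400), tolerance = 1e-12)
  expect_equal(after1$titrant_uM, 100 * 10 / 1400, tolerance = 1e-12)
  expect_equal(concentrations_after_injection(sch, 0)$titrand_uM, 50)
  expect_error(concentrations_after_injection(sch, 3), "out of range")
})

test_that("cumulative bookkeeping matches an independent loop", {
  sch <- default_schedule(syringe_conc_uM = 4600, cell_conc_uM = 115,
                          n_injections = 12)
  cs <- nmrbind:::concentration_series(sch)
  # brute-force re-implementation
  x <- 0; m <- 115; v0 <- 1400
  for (i in seq_along(sch$volumes_uL)) {
    v <- sch$volumes_uL[i]
    x <- x * (1 - v / v0) + 4600 * v / v0
    m <- m * (1 - v / v0)
  }
  expect_equal(cs$titrant_uM[12], x, tolerance = 1e-12)
  expect_equal(cs$titrand_uM[12], m, tolerance = 1e-12)
  expect_equal(cs$molar_ratio[12], x / m, tolerance = 1e-12)
})

test_that("one-site heats honour limiting cases", {
  sch <- default_schedule(syringe_conc_uM = 100, cell_conc_uM = 5000,
                          n_injections = 10, n_pre = 0)
  # zero enthalpy: all heats equal the offset
  h0 <- heats_one_site(list(n = 1, Kd_uM = 10, dH_kcal = 0,
                            q_offset_ucal = 0.3), sch)
  expect_equal(h0, rep(0.3, 10), tolerance = 1e-12)
  # tight binding into excess sites: heat = dH x moles injected
  ht <- heats_one_site(list(n = 1, Kd_uM = 0.01, dH_kcal = -10), sch)
  expect_equal(ht[1], -10 * (10 * 100 * 1e-3), tolerance = 0.05)
})

test_that("a saturating one-site titration conserves total heat", {
  # low cell loading saturates within the first few injections, so little
  # complex is displaced before equivalence and the heat sum closes the
  # budget n dH V0 [titrand]0 to < 2%
  sch <- default_schedule(syringe_conc_uM = 4600, cell_conc_uM = 115,
                          n_injections = 30)
  h <- heats_one_site(list(n = 1, Kd_uM = 0.01, dH_kcal = -10), sch)
  expect_equal(sum(h), -10 * 1.4 * 115, tolerance = 0.02)
  h2 <- heats_one_site(list(n = 0.785, Kd_uM = 0.01, dH_kcal = -10), sch)
  expect_equal(sum(h2), 0.785 * -10 * 1.4 * 115, tolerance = 0.02)
})

test_that("the sequential model collapses to one site as K2 vanishes", {
  sch <- default_schedule(syringe_conc_uM = 7000, cell_conc_uM = 800)
  h2 <- heats_two_site(list(Kd1_uM = 100, Kd2_uM = 1e15,
                            dH1_kcal = -8, dH2_kcal = 0), sch)
  h1 <- heats_one_site(list(n = 1, Kd_uM = 100, dH_kcal = -8), sch)
  expect_lt(max(abs(h2 - h1)), 1e-9)
})

test_that("the free-titrant root matches a brute-force grid scan", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      xt <- runif(1, 1, 2000); mt <- runif(1, 10, 500)
      k1 <- 1 / runif(1, 0.5, 200); k2 <- 1 / runif(1, 0.5, 200)
    })
    x <- nmrbind:::free_titrant_two_site(xt, mt, k1, k2)
    g <- function(x) {
      p <- 1 + k1 * x + k1 * k2 * x^2
      x + mt * (k1 * x + 2 * k1 * k2 * x^2) / p - xt
    }
    # bisection to high precision as the independent check
    lo <- 0; hi <- xt
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
    }
    expect_equal(x, (lo + hi) / 2, tolerance = 1e-9)
  }
})

test_that("distinct sequential steps give a biphasic heat curve", {
  sch <- default_schedule(syringe_conc_uM = 4600, cell_conc_uM = 115,
                          n_injections = 30)
  h <- heats_two_site(list(Kd1_uM = 0.05, Kd2_uM = 5,
                           dH1_kcal = -12, dH2_kcal = -4), sch)
  # per-mole heats step from dH1 through a dH2 plateau down to zero
  q_mol <- h / (sch$volumes_uL * sch$syringe_conc_uM * 1e-3)  # kcal/mol
  expect_equal(q_mol[2], -12, tolerance = 0.05)    # first step
  expect_true(any(q_mol > -5 & q_mol < -3))        # second plateau
  expect_gt(q_mol[length(q_mol)], -0.5)            # saturated tail
})

test_that("noise-free one-site fits recover the generating parameters", {
  sch <- default_schedule(syringe_conc_uM = 7000, cell_conc_uM = 800)
  iso <- gen_isotherm(list(n = 0.9, Kd_uM = 139, dH_kcal = -5), sch)
  fit <- fit_isotherm(iso)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(est[["n"]], 0.9, tolerance = 1e-3)
  expect_equal(est[["Kd_uM"]], 139, tolerance = 1e-3)
  expect_equal(est[["dH_kcal"]], -5, tolerance = 1e-3)

  # across the c range: recovery stays < 0.1%
  for (kd in c(800 * 0.9 / 5, 800 * 0.9 / 50, 800 * 0.9 / 500)) {
    iso_c <- gen_isotherm(list(n = 0.9, Kd_uM = kd, dH_kcal = -5), sch)
    f <- fit_isotherm(iso_c)
    e <- setNames(f$params$estimate, f$params$term)
    expect_equal(e[["Kd_uM"]], kd, tolerance = 1e-3)
    expect_equal(e[["n"]], 0.9, tolerance = 1e-3)
  }
})

test_that("noisy replicate fits keep the median Kd within 20%", {
  sch <- default_schedule(syringe_conc_uM = 7000, cell_conc_uM = 800)
  truth <- list(n = 0.9, Kd_uM = 139, dH_kcal = -5)
  heats0 <- heats_one_site(truth, sch)
  noise_sd <- 0.05 * max(abs(heats0))
  kds <- vapply(1:30, function(seed) {
    iso <- gen_isotherm(truth, sch, noise_sd = noise_sd, seed = seed)
    f <- tryCatch(suppressWarnings(fit_isotherm(iso)), error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    f$params$estimate[f$params$term == "Kd_uM"]
  }, numeric(1))
  expect_lt(abs(median(kds, na.rm = TRUE) - 139) / 139, 0.20)
})

test_that("fitting two-site data with a one-site model leaves structured residuals", {
  sch <- default_schedule(syringe_conc_uM = 4600, cell_conc_uM = 115,
                          n_injections = 30)
  iso <- gen_isotherm(list(Kd1_uM = 0.2, Kd2_uM = 20,
                           dH1_kcal = -12, dH2_kcal = -4), sch,
                      model_kind = "two_site_sequential",
                      noise_sd = 0.05, seed = 31)
  f1 <- suppressWarnings(fit_isotherm(iso, "one_site"))
  f2 <- fit_isotherm(iso, "two_site_sequential")
  expect_gt(f1$residual_norm, 5 * f2$residual_norm)
})

test_that("fit preconditions are enforced", {
  sch <- default_schedule(syringe_conc_uM = 7000, cell_conc_uM = 800,
                          n_injections = 8, n_pre = 1)
  iso <- gen_isotherm(list(n = 0.9, Kd_uM = 139, dH_kcal = -5), sch)
  expect_error(fit_isotherm(iso), "8 usable")
  sch2 <- default_schedule(syringe_conc_uM = 7000, cell_conc_uM = 800)
  flat <- gen_isotherm(list(n = 1, Kd_uM = 100, dH_kcal = 0), sch2)
  expect_error(fit_isotherm(flat), "flat|unidentifiable")
})

test_that("equivalence ratio lands at the stoichiometric point for tight binding", {
  sch <- default_schedule(syringe_conc_uM = 4600, cell_conc_uM = 115,
                          n_injections = 30)
  one <- gen_isotherm(list(n = 1, Kd_uM = 0.5, dH_kcal = -10), sch)
  eq1 <- equivalence_ratio(one)
  expect_false(eq1$no_transition)
  expect_lt(abs(eq1$ratio - 1), eq1$spacing)

  two <- gen_isotherm(list(Kd1_uM = 1, Kd2_uM = 1,
                           dH1_kcal = -10, dH2_kcal = -10), sch,
                      model_kind = "two_site_sequential")
  eq2 <- equivalence_ratio(two)
  expect_lt(abs(eq2$ratio - 2), eq2$spacing)

  flat <- gen_isotherm(list(n = 1, Kd_uM = 100, dH_kcal = 0), sch)
  expect_true(equivalence_ratio(flat)$no_transition)
})

test_that("dilution controls report offsets and can be subtracted before fitting", {
  sch <- default_schedule(syringe_conc_uM = 7000, cell_conc_uM = 800)
  ctrl_sch <- injection_schedule(sch$volumes_uL, sch$use_flag,
                                 syringe_conc_uM = 7000, cell_conc_uM = 1e-9)
  near_zero <- gen_isotherm(list(n = 1, Kd_uM = 100, dH_kcal = -5), ctrl_sch)
  dc <- dilution_control(near_zero)
  expect_true(dc$negligible)

  const <- near_zero
  const$heat_ucal <- const$heat_ucal - 2
  dc2 <- dilution_control(const)
  expect_false(dc2$negligible)
  expect_equal(dc2$mean_heat_ucal, -2, tolerance = 0.01)

  # subtracting a constant -2 ucal control restores the clean fit
  iso <- gen_isotherm(list(n = 0.9, Kd_uM = 139, dH_kcal = -5), sch)
  shifted <- iso
  shifted$heat_ucal <- shifted$heat_ucal - 2
  fit <- fit_isotherm(shifted, control = const)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(est[["dH_kcal"]], -5, tolerance = 0.02)
})
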