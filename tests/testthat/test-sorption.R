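test_that("uptake and removal arithmetic reproduces the batch results", {
  # IIFB: 92.4 % removal of 1.0 mg/L at 0.7 g/L dose -> 1.32 mg/g
  r <- uptake_and_removal(Ci = 1.0, Ct = 1.0 * (1 - 0.924), V = 1, W = 0.7)
  expect_equal(round(r$qt, 2), 1.32)
  expect_equal(r$removal, 92.4)
  # CFB: 87.5 % -> 1.25 mg/g
  r2 <- uptake_and_removal(Ci = 1.0, Ct = 1.0 * (1 - 0.875), V = 1, W = 0.7)
  expect_equal(round(r2$qt, 2), 1.25)
  # identity qt = Ci * removal/100 * V/W
  expect_equal(r$qt, 1.0 * r$removal / 100 * 1 / 0.7)
  # no sorption
  r0 <- uptake_and_removal(1, 1, 0.1, 0.5)
  expect_equal(r0$qt, 0); expect_equal(r0$removal, 0)
  expect_error(uptake_and_removal(0, 0, 1, 1), "positive")
  expect_error(uptake_and_removal(1, 0.5, 1, 0), "positive")
  expect_error(uptake_and_removal(1, 1.5, 1, 1), "\\[0, Ci\\]")
})

test_that("isotherm fits recover generating parameters (round trip)", {
  # parameter sets reported for the iron-impregnated and free biomass
  for (p in list(list(Qo = 1.366, b = 0.002), list(Qo = 1.004, b = 0.115))) {
    pts <- simulate_isotherm("langmuir", p, Ce = seq(0.1, 1.1, 0.1))
    fit <- fit_langmuir(pts$Ce, pts$qe)
    expect_equal(fit$Qo, p$Qo, tolerance = 1e-9)
    expect_equal(fit$b, p$b, tolerance = 1e-9)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
  }
  for (p in list(list(KF = 3.845, inv_n = 2.415),
                 list(KF = 1.412, inv_n = 1.937))) {
    pts <- simulate_isotherm("freundlich", p, Ce = seq(0.1, 1.1, 0.1))
    fit <- fit_freundlich(pts$Ce, pts$qe)
    expect_equal(fit$KF, p$KF, tolerance = 1e-9)
    expect_equal(fit$inv_n, p$inv_n, tolerance = 1e-9)
  }
})

test_that("isotherm fits reject unusable input", {
  expect_error(fit_langmuir(c(1, 2), c(1, 2)), "3")
  expect_error(fit_langmuir(c(1, -2, 3), c(1, 2, 3)), "point\\(s\\) 2")
  expect_error(fit_freundlich(c(1, 2, 3), c(1, 0, 3)), "point\\(s\\) 2")
})

test_that("Langmuir beats Freundlich on Langmuir-generated data", {
  pts <- simulate_isotherm("langmuir", list(Qo = 1.366, b = 0.9),
                           Ce = seq(0.1, 1.1, 0.05),
                           noise_sd = 0.002, seed = 31)
  expect_gte(fit_langmuir(pts$Ce, pts$qe)$r2,
             fit_freundlich(pts$Ce, pts$qe)$r2)
})

test_that("kinetic fits recover generating parameters and the h identity", {
  # pseudo-second order, both reported parameter sets
  for (p in list(list(k2p = 0.338, qe = 2.202),
                 list(k2p = 0.085, qe = 2.624))) {
    ser <- simulate_kinetics("pso", p, t = seq(5, 135, 10))
    fit <- fit_pso(ser$t, ser$qt)
    expect_equal(fit$k2p, p$k2p, tolerance = 1e-6)
    expect_equal(fit$qe, p$qe, tolerance = 1e-6)
    expect_equal(fit$h, fit$k2p * fit$qe^2)   # exact identity
  }
  # initial sorption rates implied by the reported constants
  expect_equal(0.338 * 2.202^2, 1.639, tolerance = 1e-3)
  expect_equal(0.085 * 2.624^2, 0.585, tolerance = 1e-3)

  # pseudo-first order round trip
  ser <- simulate_kinetics("pfo", list(ks = 0.03, qe = 2.0),
                           t = seq(5, 135, 10))
  fit <- fit_pfo(ser$t, ser$qt, qe_obs = 2.0)
  expect_equal(fit$ks, 0.03, tolerance = 1e-3)
  expect_equal(fit$qe, 2.0, tolerance = 1e-3)
})

test_that("kinetic fits flag degenerate or truncated input", {
  expect_warning(fit <- fit_pso(1:5, rep(2.2, 5)), "equilibrium")
  expect_true(fit$degenerate)
  expect_equal(fit$qe, 2.2, tolerance = 1e-9)

  # PFO drops points at/above the observed equilibrium
  ser <- simulate_kinetics("pfo", list(ks = 0.05, qe = 2), t = seq(10, 130, 15))
  qt <- ser$qt; qt[7] <- 2.1
  expect_warning(fit_pfo(ser$t, qt, qe_obs = 2), "excluded")
})

test_that("Van't Hoff analysis matches hand thermodynamics", {
  # Kc = 1 everywhere: all energies vanish
  th0 <- vant_hoff(c(293, 303, 313), c(1, 1, 1))
  expect_equal(th0$per_T$dG_kJ_mol, c(0, 0, 0))
  expect_equal(th0$dH_kJ_mol, 0, tolerance = 1e-12)
  expect_equal(th0$dS_kJ_mol_K, 0, tolerance = 1e-12)

  # single-point Gibbs energy, hand arithmetic: -8.314*298*ln(2)/1000
  th1 <- vant_hoff(c(298, 308, 318), c(2, 2, 2))
  expect_equal(th1$per_T$dG_kJ_mol[1], -8.314 * 298 * log(2) / 1000)
  expect_equal(round(th1$per_T$dG_kJ_mol[1], 3), -1.717)

  # exact recovery of generating enthalpy/entropy (reported parameter set)
  sim <- simulate_vanthoff(dH = 46.749, dS = 0.162)
  th <- vant_hoff(sim$T_K, sim$Kc)
  expect_equal(th$dH_kJ_mol, 46.749, tolerance = 1e-9)
  expect_equal(th$dS_kJ_mol_K, 0.162, tolerance = 1e-9)
  expect_equal(th$r2_vanthoff, 1, tolerance = 1e-9)
  # dG consistency with stored Kc
  expect_equal(th$per_T$dG_kJ_mol,
               -8.314 * sim$T_K * log(sim$Kc) / 1000)

  expect_error(vant_hoff(c(298, 308), c(1, 2)), "3")
  expect_error(vant_hoff(c(298, 308, 318), c(1, -2, 3)), "positive")
})

test_that("noisy generate-and-refit stays estimator-consistent", {
  # averaged over seeds, parameters are recovered within a few percent
  est <- t(vapply(1:20, function(s) {
    pts <- simulate_isotherm("langmuir", list(Qo = 1.366, b = 0.9),
                             Ce = seq(0.1, 1.1, 0.05),
                             noise_sd = 0.001, seed = s)
    fit <- fit_langmuir(pts$Ce, pts$qe)
    c(fit$Qo, fit$b)
  }, numeric(2)))
  expect_equal(mean(est[, 1]), 1.366, tolerance = 0.02)
  expect_equal(mean(est[, 2]), 0.9, tolerance = 0.05)
})
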