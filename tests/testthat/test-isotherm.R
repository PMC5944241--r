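test_that("Gouy-Chapman potential matches an independent closed form", {
  expect_equal(gc_potential(0), 0)
  # independent tanh-parameterization oracle at several charges
  for (s in c(-0.2, -0.1, -0.02, 0.05, 0.15)) {
    expect_equal(gc_potential(s),
                 oracle_gc_potential(s, 0.1, 298.15, 78.2),
                 tolerance = 1e-10)
  }
  expect_equal(gc_potential(-0.1) * 1e3, -88.3, tolerance = 0.001)
  # odd and strictly monotone
  sig <- seq(-0.3, 0.3, by = 0.01)
  expect_equal(gc_potential(-sig), -gc_potential(sig))
  expect_true(all(diff(gc_potential(sig)) > 0))
})

test_that("Gouy-Chapman potential linearizes to Debye-Huckel at small charge", {
  gc <- gc_params()
  sig_star <- sqrt(8 * gc$eps_r * ORC$eps0 * ORC$kB * gc$temperature *
                     1000 * ORC$N_A * gc$c_elec)
  slope <- 2 * ORC$kB * gc$temperature / (ORC$e * sig_star)
  for (s in c(0.01, 0.05, 0.09) * sig_star) {
    expect_equal(gc_potential(s, gc), slope * s, tolerance = 0.01)
  }
})

test_that("Hill coverage has the required special values and shape", {
  for (n in c(0.3, 0.54, 1, 2)) {
    expect_equal(hill_coverage(1 / 2e6, 2e6, n), 0.5)
  }
  # n = 1 is exactly Langmuir
  cc <- 10^seq(-9, -3, length.out = 20)
  expect_equal(hill_coverage(cc, 1e6, 1), 1e6 * cc / (1 + 1e6 * cc))
  expect_equal(hill_coverage(1e-6, 1.6e6, 0.54), 0.563, tolerance = 0.001)
  expect_true(all(diff(hill_coverage(cc, 1e6, 0.5)) > 0))
})

test_that("model E-field is normalized, monotone, and A/B scale-invariant", {
  gc <- gc_params()
  pars <- list(A = 1, B = -5, K_ads = 1.6e6, n = 0.54, dsigma = 0.10,
               sigma0 = -0.1)
  expect_equal(model_efield(0, pars, gc), 1)
  # no adsorbed charge: flat response
  p0 <- modifyList(pars, list(dsigma = 0))
  expect_equal(model_efield(10^seq(-8, -2), p0, gc), rep(1, 7))
  # cation adsorption on an anionic bilayer decreases the signal
  cc <- 10^seq(-9, -1, length.out = 30)
  E <- model_efield(cc, pars, gc)
  expect_true(all(diff(E) < 0))
  # charge-neutralized plateau at theta = 1
  plateau <- pars$A / (pars$A + pars$B * gc_potential(pars$sigma0, gc))
  expect_equal(model_efield(1e3, pars, gc), plateau, tolerance = 1e-3)
  # joint rescaling of A and B leaves the normalized field unchanged
  p2 <- modifyList(pars, list(A = 7, B = -35))
  expect_equal(model_efield(cc, p2, gc), E)
})

test_that("extrapolated saturation point follows the trailing-average rule", {
  iso <- isotherm_data(c(1e-7, 1e-6, 1e-5, 1e-4, 1e-3),
                       c(0.95, 0.90, 0.80, 0.82, 0.84))
  aug <- augment_extrapolated(iso, c_extrap = 0.1, k = 3)
  expect_equal(nrow(aug), 6)
  expect_equal(aug$conc_M[6], 0.1)
  expect_equal(aug$E_norm[6], mean(c(0.80, 0.82, 0.84)))
  expect_true(aug$extrapolated[6])
  # k = 1 copies the last point
  aug1 <- augment_extrapolated(iso, k = 1)
  expect_equal(aug1$E_norm[6], 0.84)
  # augmenting twice is rejected
  expect_error(augment_extrapolated(aug), "already contains")
  expect_error(augment_extrapolated(iso[1:2, ], k = 3), "at least k")
})

test_that("isotherm fit recovers known parameters from synthetic data", {
  spec <- scenario_spec(K_ads = 1.5e6, n = 0.5, dsigma = 0.10)
  # noiseless: exact recovery within optimizer tolerance, ~zero residual
  spec0 <- scenario_spec(K_ads = 1.5e6, n = 0.5, dsigma = 0.10,
                         noise_E = 0)
  iso0 <- sim_isotherm(spec0, seed = 1)
  f0 <- hillgc(iso0)
  expect_lt(f0$deviance, 1e-6)
  expect_equal(coef(f0)[["K_ads"]], 1.5e6, tolerance = 1e-3)
  expect_equal(coef(f0)[["n"]], 0.5, tolerance = 1e-3)
  expect_equal(coef(f0)[["dsigma"]], 0.10, tolerance = 1e-3)
  # 1% noise with the extrapolated point: within 20%
  iso <- sim_isotherm(spec, seed = 11)
  f <- hillgc(augment_extrapolated(iso), fix_B = spec$B)
  expect_equal(coef(f)[["K_ads"]], 1.5e6, tolerance = 0.2)
  expect_equal(coef(f)[["n"]], 0.5, tolerance = 0.2)
  expect_equal(coef(f)[["dsigma"]], 0.10, tolerance = 0.2)
  expect_true(f$converged)
})

test_that("a flat isotherm yields dsigma consistent with zero", {
  set.seed(5)
  cc <- 10^seq(-8, -2, length.out = 12)
  iso <- isotherm_data(cc, 1 + rnorm(12, 0, 0.005), sigma_E = 0.005)
  f <- hillgc(iso, fix_B = -5)
  expect_lt(abs(coef(f)[["dsigma"]]),
            max(c(3 * sqrt(f$vcov["dsigma", "dsigma"]), 0.02),
                na.rm = TRUE))
})

test_that("fits with and without the extrapolated point agree within 1 SE", {
  spec <- scenario_spec()
  iso <- sim_isotherm(spec, conc = 10^seq(-8, -2, length.out = 16),
                      seed = 21)
  f_no <- hillgc(iso, fix_B = spec$B)
  f_yes <- hillgc(augment_extrapolated(iso), fix_B = spec$B)
  for (p in c("K_ads", "n", "dsigma")) {
    se <- sqrt(f_no$vcov[p, p] + f_yes$vcov[p, p])
    expect_lt(abs(coef(f_no)[[p]] - coef(f_yes)[[p]]), 2 * se)
  }
})

test_that("sensitivity scan brackets the central fit and widens with perturbation", {
  spec <- scenario_spec()
  iso <- augment_extrapolated(sim_isotherm(spec, seed = 31))
  f <- hillgc(iso, fix_B = spec$B)
  sc <- sensitivity_scan(f, 0.10)
  expect_true(coef(f)[["dsigma"]] >= sc$dsigma_range[1] &&
                coef(f)[["dsigma"]] <= sc$dsigma_range[2])
  expect_true(coef(f)[["K_ads"]] >= sc$K_range[1] &&
                coef(f)[["K_ads"]] <= sc$K_range[2])
  # zero perturbation degenerates to the central fit
  sc0 <- sensitivity_scan(f, 0)
  expect_equal(diff(sc0$dsigma_range), 0, tolerance = 1e-8)
  # range width grows with the perturbation (noiseless data)
  spec0 <- scenario_spec(noise_E = 0)
  iso0 <- augment_extrapolated(sim_isotherm(spec0, seed = 1))
  f0 <- hillgc(iso0, fix_B = spec0$B)
  w <- vapply(c(0.05, 0.10, 0.20), function(p) {
    diff(sensitivity_scan(f0, p)$dsigma_range)
  }, numeric(1))
  expect_true(all(diff(w) > 0))
  expect_error(sensitivity_scan(hillgc(sim_isotherm(spec, seed = 2))),
               "no extrapolated")
})

test_that("free energy conversion uses the 55.5 M reference state", {
  expect_equal(adsorption_free_energy(1.6e6), -45, tolerance = 0.01)
  expect_equal(adsorption_free_energy(1.0e6), -44, tolerance = 0.01)
  expect_equal(adsorption_free_energy(1 / 55.5), 0)
  expect_equal(additive_free_energy(-5.9, 8), -47.2)
  expect_equal(additive_free_energy(-3.1, 1), -3.1)
  expect_equal(additive_free_energy(-5.9, 9), -53.1)
})

test_that("percent ionization is a guarded ratio", {
  expect_equal(percent_ionization(0.08, 0.08), 100)
  expect_equal(percent_ionization(0, 0.05), 0)
  expect_equal(percent_ionization(0.08, 0.079), 101.3, tolerance = 0.001)
  expect_error(percent_ionization(0.05, 0), "> 0")
})

test_that("hillgc methods are coherent", {
  spec <- scenario_spec()
  iso <- augment_extrapolated(sim_isotherm(spec, seed = 41))
  f <- hillgc(iso, fix_B = spec$B)
  expect_equal(unname(fitted(f)), unname(predict(f)))
  expect_equal(length(residuals(f)), nrow(iso))
  expect_output(print(f), "K_ads")
  expect_output(print(summary(f)), "dG_ads")
  sims <- simulate(f, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(nrow(iso), 3L))
  # weighted residuals of the fit are centred near zero
  expect_lt(abs(mean(residuals(f))), 1)
})
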