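test_that("charge integration satisfies analytic pulse and neutrality checks", {
  z <- seq(0, 50, by = 0.5)
  zero <- charge_profile(z, list(ions = rep(0, length(z))))
  expect_true(all(integrate_charge(zero)$sigma == 0))

  # square pulse of total areal charge q plateaus at q
  rho <- ifelse(z >= 10 & z <= 20, 2e7, 0)   # C m^-3 over 10 A
  prof <- charge_profile(z, list(peptide = rho))
  sig <- integrate_charge(prof, "peptide")
  q <- 2e7 * 10e-10
  expect_equal(sig$sigma[length(z)], q, tolerance = 0.06)
  expect_equal(sig$sigma[z == 30], sig$sigma[length(z)])

  # cumulative trapezoid agrees with a hand-rolled loop oracle
  expect_equal(sig$sigma, oracle_cumtrapz(z * 1e-10, rho))

  # synthetic Gouy-Chapman ion cloud carries the counter-charge
  prof_gc <- sim_gc_profile(sigma0 = -0.1)
  ions <- integrate_charge(prof_gc, "ions")
  expect_equal(ions$sigma[nrow(ions)], 0.1, tolerance = 1e-6)
  # and the full profile is neutral
  tot <- integrate_charge(prof_gc, "total")
  expect_lt(abs(tot$sigma[nrow(tot)]), 1e-9 * 0.1)
  expect_error(charge_profile(c(0, 1, 3, 4), list(a = rep(1, 4))),
               "non-uniform")
})

test_that("Poisson potential reproduces the parallel-plate closed form", {
  z <- seq(0, 10, by = 0.05)
  rho <- numeric(length(z))
  s <- 0.05                               # C m^-2 per sheet
  rho[z == 3] <- s / 0.05e-10
  rho[z == 7] <- -s / 0.05e-10
  prof <- charge_profile(z, list(lipid = rho))
  pot <- poisson_potential(prof)
  dphi <- pot$phi[z == 3.5] - pot$phi[z == 6.5]
  expect_equal(dphi, s * 3e-10 / ORC$eps0, tolerance = 0.01)
  # zero density gives zero potential
  p0 <- poisson_potential(charge_profile(z, list(a = numeric(length(z)))))
  expect_true(all(p0$phi == 0))
})

test_that("Poisson potential is linear in the charge density", {
  p1 <- sim_gc_profile(sigma0 = -0.05)
  p2 <- sim_gc_profile(sigma0 = -0.05, dipole = 0.02)
  both <- charge_profile(p1$z_A, list(
    a = p1$rho_total + p2$rho_total))
  expect_equal(poisson_potential(both)$phi,
               poisson_potential(p1)$phi + poisson_potential(p2)$phi,
               tolerance = 1e-8)
})

test_that("non-neutral profiles trigger a boundary-field warning", {
  z <- seq(0, 30, by = 0.5)
  rho <- ifelse(z >= 10 & z <= 12, 1e7, 0)
  expect_warning(poisson_potential(charge_profile(z, list(q = rho))),
                 "not neutral")
})

test_that("Grahame equation inverts the Gouy-Chapman potential exactly", {
  expect_equal(grahame_sigma(0), 0)
  for (gc in list(gc_params(), gc_params(303.15, 0.15, 27))) {
    for (s in c(-0.2, -0.1, -0.01, 0.03, 0.12)) {
      expect_equal(grahame_sigma(gc_potential(s, gc), gc), s,
                   tolerance = 1e-12)
    }
  }
  expect_equal(grahame_sigma(-0.0883), -0.1, tolerance = 0.01)
})

test_that("integrated Poisson potential matches the analytic GC solution", {
  prof <- sim_gc_profile(sigma0 = -0.1,
                         gc = gc_params(303.15, 0.15, 78.2))
  tr <- attr(prof, "truth")
  pot <- poisson_potential(prof)
  sel <- prof$z_A >= tr$z0 + 1 & prof$z_A <= tr$z0 + 25
  err <- max(abs(pot$phi[sel] - tr$phi_of_z(prof$z_A[sel])))
  expect_lt(err / abs(tr$phi0), 0.01)
})

test_that("apparent-dielectric fit recovers the ground truth permittivity", {
  for (eps in c(10, 27, 78)) {
    for (ce in c(0.1, 0.15)) {
      for (s0 in c(-0.05, -0.1)) {
        prof <- sim_gc_profile(sigma0 = s0,
                               gc = gc_params(303.15, ce, eps))
        pot <- poisson_potential(prof)
        sig <- integrate_charge(prof, c("lipid", "ions"))
        gf <- grahame_fit(pot, sig, window = c(20.5, 26), c_elec = ce)
        expect_equal(gf$eps_app, eps, tolerance = 0.05)
      }
    }
  }
})

test_that("degenerate or ill-posed dielectric fits are rejected", {
  prof <- sim_gc_profile(sigma0 = 0)
  pot <- poisson_potential(prof)
  sig <- integrate_charge(prof, c("lipid", "ions"))
  expect_error(grahame_fit(pot, sig, window = c(20.5, 26)), "degenerate")
  prof2 <- sim_gc_profile(sigma0 = -0.1)
  expect_error(grahame_fit(poisson_potential(prof2),
                           integrate_charge(prof2, c("lipid", "ions")),
                           window = c(200, 210)), ">= 3 grid points")
})

test_that("bound-monomer counts match the brute-force all-pairs oracle", {
  # hand-placed boundary case: inclusive at the cutoff
  P <- data.frame(x = 10, y = 10, z = 0)
  sc <- data.frame(peptide = 1, type = "ARG", x = 10, y = 10, z = 5.5)
  g <- binding_geometry(sc, P, box = c(50, 50, 50))
  expect_equal(bound_monomers(g)$per_peptide$n_bound, 1)
  sc$z <- 5.6
  g2 <- binding_geometry(sc, P, box = c(50, 50, 50))
  expect_equal(bound_monomers(g2)$per_peptide$n_bound, 0)
  # empty geometry
  g0 <- binding_geometry(sc[0, ], P, box = c(50, 50, 50))
  expect_equal(bound_monomers(g0)$n_bound_peptides, 0)

  # randomized fixtures against the explicit 27-image loop oracle
  set.seed(123)
  for (rep in 1:6) {
    n_pep <- 6
    sc <- data.frame(
      peptide = rep(seq_len(n_pep), each = 8),
      type = sample(c("ARG", "LYS"), 8 * n_pep, replace = TRUE),
      x = runif(8 * n_pep, -20, 120), y = runif(8 * n_pep, -20, 120),
      z = runif(8 * n_pep, 0, 15))
    P <- data.frame(x = runif(30, 0, 100), y = runif(30, 0, 100),
                    z = runif(30, 0, 4))
    g <- binding_geometry(sc, P, box = c(100, 100, 60))
    bm <- bound_monomers(g)
    expect_identical(bm$per_peptide$n_bound, oracle_bound_counts(g))
  }
})

test_that("planted binding fixtures are recovered exactly", {
  planted <- c(rep(3, 10), rep(5, 10))
  g <- sim_binding_geometry(planted, type = "ARG", seed = 8)
  bm <- bound_monomers(g)
  expect_equal(bm$per_peptide$n_bound, planted)
  expect_equal(as.integer(bm$histogram[c("3", "5")]), c(10L, 10L))
  expect_equal(bm$n_bound_peptides, 20L)
  # all-zero planting
  g0 <- sim_binding_geometry(rep(0, 5), seed = 9)
  expect_equal(sum(bound_monomers(g0)$per_peptide$n_bound), 0)
  # zero margin with boundary placement: counted as bound (inclusive)
  gb <- sim_binding_geometry(c(2, 2), margin = 0, at_boundary = TRUE,
                             seed = 10)
  expect_equal(bound_monomers(gb)$per_peptide$n_bound, c(2, 2))
})
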