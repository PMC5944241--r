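# Synthetic-data generators with known ground truth for every input class
# the analysis stages consume: QCM-D/LSPR traces, SHG isotherms, planar
# Gouy-Chapman charge-density profiles, and binding-geometry fixtures.
# All generators are deterministic for a fixed seed.

#' Scenario specification: ground truth for the generators
#'
#' Defaults describe the Arg8 study conditions: acoustic mass 210 and
#' optical mass 13 ng cm^-2, binding constant 1.6e6 M^-1, Hill
#' coefficient 0.54, peptide-added charge 0.10 C m^-2 on a bilayer of
#' initial charge -0.1 C m^-2 in 0.1 M 1:1 electrolyte. The Kelvin-Voigt
#' layer truth uses a 1050 kg m^-3 film of the thickness implied by the
#' acoustic mass, with soft-film viscoelasticity typical of highly
#' hydrated peptide adlayers.
#'
#' @param peptide A [peptide_descriptor()] or its shortcut string.
#' @param K_ads,n,dsigma,sigma0 Isotherm truth (M^-1, -, C m^-2, C m^-2).
#' @param B SHG potential-response coefficient (V^-1, with A = 1).
#' @param mass_acoustic,mass_optical Plateau masses in ng cm^-2.
#' @param rate_k Adsorption rate constant in s^-1 for the
#'   exponential-saturation kinetics.
#' @param rho_film,eta_film,mu_film Kelvin-Voigt film truth (kg m^-3,
#'   kg m^-1 s^-1, Pa).
#' @param optics An [optical_params()].
#' @param gc A [gc_params()].
#' @param noise_f,noise_D,noise_dlambda,noise_E Per-channel noise levels:
#'   additive Gaussian SD for frequency (Hz), dissipation (absolute) and
#'   wavelength (nm); multiplicative CV for the SHG E-field.
#' @return List of class `"scenario_spec"`.
#' @export
scenario_spec <- function(peptide = "ARG8", K_ads = 1.6e6, n = 0.54,
                          dsigma = 0.10, sigma0 = -0.1, B = -5,
                          mass_acoustic = 210, mass_optical = 13,
                          rate_k = 1 / 300,
                          rho_film = 1050, eta_film = 1.5e-3,
                          mu_film = 1e5,
                          optics = optical_params(d = 2),
                          gc = gc_params(),
                          noise_f = 0.2, noise_D = 0.05e-6,
                          noise_dlambda = 0.002, noise_E = 0.01) {
  if (is.character(peptide)) peptide <- peptide_descriptor(peptide)
  structure(list(peptide = peptide, K_ads = K_ads, n = n, dsigma = dsigma,
                 sigma0 = sigma0, B = B, mass_acoustic = mass_acoustic,
                 mass_optical = mass_optical, rate_k = rate_k,
                 rho_film = rho_film, eta_film = eta_film,
                 mu_film = mu_film, optics = optics, gc = gc,
                 noise_f = noise_f, noise_D = noise_D,
                 noise_dlambda = noise_dlambda, noise_E = noise_E),
            class = "scenario_spec")
}

#' Simulate paired QCM-D and LSPR adsorption traces
#'
#' Exponential-saturation kinetics
#' `Gamma(t) = Gamma_max * (1 - exp(-k*(t - t0)))` mapped through the
#' Kelvin-Voigt forward model (per harmonic) and the inverse de Feijter
#' relation, plus additive Gaussian noise per channel.
#'
#' @param spec A [scenario_spec()].
#' @param times Sample times in s.
#' @param t0 Injection time in s.
#' @param harmonics Harmonics to simulate.
#' @param seed RNG seed.
#' @return List with `qcmd` (columns `time_s`, `harmonic`, `df_Hz`, `dD`),
#'   `lspr` (columns `time_s`, `dlambda_nm`) and `spec`.
#' @export
sim_qcmd_lspr <- function(spec = scenario_spec(),
                          times = seq(0, 3600, by = 30), t0 = 300,
                          harmonics = c(7, 9, 11), seed = 1) {
  set.seed(seed)
  frac <- pmax(0, 1 - exp(-spec$rate_k * (times - t0)))
  gam_ac <- spec$mass_acoustic * frac          # ng cm^-2
  gam_op <- spec$mass_optical * frac

  qcmd <- do.call(rbind, lapply(seq_along(times), function(i) {
    if (gam_ac[i] <= 0) {
      data.frame(harmonic = harmonics, df_Hz = 0, dD = 0)
    } else {
      layer <- viscoelastic_layer(h = gam_ac[i] * 1e-8 / spec$rho_film,
                                  rho = spec$rho_film,
                                  eta = spec$eta_film, mu = spec$mu_film)
      kelvin_voigt_forward(layer, harmonics = harmonics)
    }
  }))
  qcmd <- cbind(time_s = rep(times, each = length(harmonics)), qcmd)
  qcmd$df_Hz <- qcmd$df_Hz + stats::rnorm(nrow(qcmd), 0, spec$noise_f)
  qcmd$dD <- qcmd$dD + stats::rnorm(nrow(qcmd), 0, spec$noise_D)

  # invert the de Feijter relation for the wavelength shift
  geom <- if (is.null(spec$optics$d)) spec$optics$L else
    spec$optics$d / (1 - exp(-spec$optics$d / spec$optics$L))
  dlambda <- gam_op / 100 * spec$optics$S * spec$optics$dndc / geom
  lspr <- data.frame(
    time_s = times,
    dlambda_nm = dlambda + stats::rnorm(length(times), 0,
                                        spec$noise_dlambda))
  list(qcmd = qcmd, lspr = lspr, spec = spec)
}

#' Simulate an SHG adsorption isotherm
#'
#' Evaluates the Hill/Gouy-Chapman model at the scenario truth and applies
#' multiplicative Gaussian noise.
#'
#' @param spec A [scenario_spec()].
#' @param conc Positive increasing concentrations in mol L^-1.
#' @param seed RNG seed.
#' @return An [isotherm_data()]; the truth parameters are attached as
#'   attribute `"truth"`.
#' @export
sim_isotherm <- function(spec = scenario_spec(),
                         conc = 10^seq(-8, -2, length.out = 12),
                         seed = 1) {
  set.seed(seed)
  pars <- list(A = 1, B = spec$B, K_ads = spec$K_ads, n = spec$n,
               dsigma = spec$dsigma, sigma0 = spec$sigma0)
  mu <- model_efield(conc, pars, spec$gc)
  E <- mu * (1 + stats::rnorm(length(mu), 0, spec$noise_E))
  iso <- isotherm_data(conc, E, sigma_E = pmax(spec$noise_E, 1e-4) *
                         abs(mu))
  attr(iso, "truth") <- pars
  iso
}

#' Analytic planar Gouy-Chapman charge-density profile
#'
#' Builds a component-resolved profile whose vacuum-permittivity Poisson
#' potential equals the analytic Gouy-Chapman potential for dielectric
#' constant `eps_true`: a `lipid` surface-charge sheet `sigma0` at `z0`,
#' the Boltzmann counter-ion cloud (`ions`), and the solvent bound
#' (polarization) charge (`water`) consisting of a volume term
#' `-(eps-1)/eps` times the ion charge plus a surface bound sheet
#' `-(eps-1)/eps * sigma0`. The ion cloud is rescaled (by < 1e-6) so the
#' full profile integrates to zero exactly under the trapezoid rule.
#' With this construction, [grahame_fit()] on the non-water cumulative
#' charge and the full-profile potential recovers `eps_true`.
#'
#' @param sigma0 Surface charge density in C m^-2.
#' @param gc A [gc_params()] whose `eps_r` is the ground-truth dielectric
#'   constant.
#' @param z0 Surface plane position in Angstrom.
#' @param z_max Grid extent in Angstrom.
#' @param dz Grid spacing in Angstrom.
#' @param dipole Optional water-dipole areal charge (C m^-2); adds a
#'   net-neutral +/- sheet pair inside the membrane region to the water
#'   component to exercise component decomposition.
#' @return A [charge_profile()] with attribute `"truth"` (list with
#'   `phi0`, `eps_true`, `kappa_inv_A`, `z0`).
#' @export
sim_gc_profile <- function(sigma0 = -0.1,
                           gc = gc_params(temperature = 303.15,
                                          c_elec = 0.15, eps_r = 27),
                           z0 = 20, z_max = 80, dz = 0.1, dipole = 0) {
  z <- seq(0, z_max, by = dz)
  nzz <- length(z)
  kT <- .const$kB * gc$temperature
  n0 <- 1000 * .const$N_A * gc$c_elec
  lipid <- ions <- water <- numeric(nzz)
  i0 <- which.min(abs(z - z0))
  dz_m <- dz * 1e-10

  if (sigma0 != 0) {
    phi0 <- gc_potential(sigma0, gc)
    kappa <- sqrt(2 * n0 * .const$e^2 / (gc$eps_r * .const$eps0 * kT))
    gam <- tanh(.const$e * phi0 / (4 * kT))
    phi_of_z <- function(zz) {
      4 * kT / .const$e * atanh(gam * exp(-kappa * (zz - z0) * 1e-10))
    }
    diffuse <- z >= z0
    phi_d <- phi_of_z(z[diffuse])
    rho_ion <- -2 * .const$e * n0 * sinh(.const$e * phi_d / kT)
    rho_ion[1] <- rho_ion[1] / 2  # half contact value at the jump
    ions[diffuse] <- rho_ion
    # exact trapezoid neutrality: ion cloud must integrate to -sigma0
    tot <- as.numeric(utils::tail(pracma::cumtrapz(z * 1e-10, ions), 1))
    ions <- ions * (-sigma0 / tot)
    lipid[i0] <- sigma0 / dz_m
    water <- -(gc$eps_r - 1) / gc$eps_r * ions
    water[i0] <- water[i0] - (gc$eps_r - 1) / gc$eps_r * sigma0 / dz_m
    truth <- list(phi0 = phi0, eps_true = gc$eps_r,
                  kappa_inv_A = 1e10 / kappa, z0 = z0,
                  phi_of_z = phi_of_z)
  } else {
    truth <- list(phi0 = 0, eps_true = gc$eps_r, kappa_inv_A = NA_real_,
                  z0 = z0, phi_of_z = function(zz) rep(0, length(zz)))
  }
  if (dipole != 0) {
    ip <- which.min(abs(z - (z0 - 5)))
    im <- which.min(abs(z - (z0 - 3)))
    water[ip] <- water[ip] + dipole / dz_m
    water[im] <- water[im] - dipole / dz_m
  }
  prof <- charge_profile(z, list(lipid = lipid, ions = ions,
                                 water = water))
  attr(prof, "truth") <- truth
  prof
}

#' Simulate a binding-geometry fixture with planted bound counts
#'
#' Places representative sidechain atoms so that each peptide has exactly
#' its planted number of sidechains within the binding cutoff of some
#' lipid phosphorus, with the remaining sidechains strictly farther than
#' `cutoff + margin` from every phosphorus.
#'
#' @param planted Integer vector (one per peptide) of bound-sidechain
#'   counts in 0..`n_side`.
#' @param type Residue type per peptide (`"ARG"` or `"LYS"`, recycled).
#' @param n_side Sidechains per peptide (default 8).
#' @param box Length-3 box in Angstrom; phosphorus atoms lie in the
#'   z = 0 plane.
#' @param cutoffs Named cutoffs in Angstrom.
#' @param margin Clearance in Angstrom separating unbound sidechains from
#'   the cutoff sphere.
#' @param at_boundary If `TRUE`, bound sidechains are placed at exactly
#'   the cutoff distance (tests the inclusive boundary convention).
#' @param seed RNG seed.
#' @return A [binding_geometry()] with attribute `"planted"`.
#' @export
sim_binding_geometry <- function(planted, type = "ARG", n_side = 8,
                                 box = c(100, 100, 240),
                                 cutoffs = c(ARG = 5.5, LYS = 4.5),
                                 margin = 1, at_boundary = FALSE,
                                 seed = 1) {
  stopifnot(all(planted >= 0), all(planted <= n_side))
  set.seed(seed)
  type <- rep_len(type, length(planted))
  ngrid <- 8
  gxy <- seq(box[1] / (2 * ngrid), box[1], by = box[1] / ngrid)
  P <- expand.grid(x = gxy, y = gxy)
  P$z <- 0

  sc <- do.call(rbind, lapply(seq_along(planted), function(i) {
    rc <- cutoffs[[type[i]]]
    k <- planted[i]
    rows <- vector("list", n_side)
    for (j in seq_len(n_side)) {
      if (j <= k) {
        pidx <- sample.int(nrow(P), 1)
        d <- if (at_boundary) rc else rc * stats::runif(1, 0.3, 0.95)
        rows[[j]] <- data.frame(peptide = i, type = type[i],
                                x = P$x[pidx], y = P$y[pidx], z = d)
      } else {
        rows[[j]] <- data.frame(
          peptide = i, type = type[i],
          x = stats::runif(1, 0, box[1]), y = stats::runif(1, 0, box[2]),
          z = max(cutoffs) + margin + 1e-6 + stats::runif(1, 0, 20))
      }
    }
    do.call(rbind, rows)
  }))
  if (is.null(sc)) {
    sc <- data.frame(peptide = integer(), type = character(),
                     x = numeric(), y = numeric(), z = numeric())
  }
  geom <- binding_geometry(sc, P, box, cutoffs)
  attr(geom, "planted") <- planted
  geom
}
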