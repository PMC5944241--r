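# Interfacial electrostatics from simulation-derived charge-density
# profiles: cumulative charge, Poisson potential, Grahame-equation fits
# for an apparent interfacial dielectric constant, and bound-sidechain
# counting from representative-atom coordinates.

#' Construct a z-binned, component-resolved charge-density profile
#'
#' @param z Uniform grid of bin centers along the membrane normal, in
#'   Angstrom, with the bilayer center at z = 0.
#' @param rho Named list or matrix of per-component charge densities on
#'   the grid (components such as `lipid`, `ions`, `water`, `peptide`).
#'   A `total` column is appended as the row sum if absent.
#' @param units `"C_m3"` or `"e_A3"`; densities are stored in C m^-3.
#' @param area Box cross-section area in Angstrom^2 (metadata).
#' @return Data frame of class `"charge_profile"` with column `z_A` and
#'   one `rho_<component>` column per component (C m^-3).
#' @export
charge_profile <- function(z, rho, units = c("C_m3", "e_A3"),
                           area = NA_real_) {
  units <- match.arg(units)
  rho <- as.data.frame(rho)
  stopifnot(nrow(rho) == length(z), length(z) >= 3)
  dz <- diff(z)
  if (max(abs(dz - dz[1])) > 1e-8 * abs(dz[1])) {
    stop("non-uniform z grid: resample before constructing the profile",
         call. = FALSE)
  }
  if (units == "e_A3") rho <- rho * (.const$e / 1e-30)
  if (!"total" %in% names(rho)) rho$total <- rowSums(rho)
  tot_err <- max(abs(rho$total - rowSums(rho[setdiff(names(rho), "total")])))
  if (tot_err > 1e-6 * max(abs(as.matrix(rho)), 1e-300)) {
    stop("total component is not the sum of the parts", call. = FALSE)
  }
  names(rho) <- paste0("rho_", names(rho))
  out <- cbind(data.frame(z_A = z), rho)
  attr(out, "area_A2") <- area
  class(out) <- c("charge_profile", "data.frame")
  out
}

.profile_components <- function(profile) {
  sub("^rho_", "", grep("^rho_", names(profile), value = TRUE))
}

.profile_rho <- function(profile, components) {
  if (identical(components, "total")) return(profile$rho_total)
  bad <- setdiff(components, .profile_components(profile))
  if (length(bad)) stop("unknown component(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  rowSums(profile[, paste0("rho_", components), drop = FALSE])
}

#' Cumulative charge density integrated from the bilayer center
#'
#' `sigma(z) = integral_0^z rho(z') dz'` by the trapezoid rule, for a
#' selected component or sum of components. For the total, neutrality
#' makes `sigma` vanish at the far edge of the box.
#'
#' @param profile A [charge_profile()].
#' @param components Character vector of component names, or `"total"`.
#' @return Data frame with `z_A` and `sigma` (C m^-2).
#' @export
integrate_charge <- function(profile, components = "total") {
  rho <- .profile_rho(profile, components)
  z_m <- profile$z_A * 1e-10
  data.frame(z_A = profile$z_A,
             sigma = as.numeric(pracma::cumtrapz(z_m, rho)))
}

#' Electrostatic potential by double integration of the charge density
#'
#' `phi(z) = -(1/eps0) * int_0^z dz' int_0^z' rho(z'') dz''`, using the
#' vacuum permittivity (all charges, including solvent, are explicit in
#' the profile), then shifted so the potential averages to zero over the
#' bulk region (last `bulk_frac` of the grid). A non-neutral profile
#' leaves a residual field at the boundary and triggers a warning.
#'
#' @param profile A [charge_profile()].
#' @param components Component selection as in [integrate_charge()].
#' @param bulk_frac Trailing fraction of the grid treated as bulk for the
#'   zero reference.
#' @return Data frame with `z_A` and `phi` (V).
#' @export
poisson_potential <- function(profile, components = "total",
                              bulk_frac = 0.1) {
  sig <- integrate_charge(profile, components)
  z_m <- profile$z_A * 1e-10
  if (identical(components, "total")) {
    scale <- max(vapply(.profile_components(profile), function(comp) {
      max(abs(integrate_charge(profile, comp)$sigma))
    }, numeric(1)), 1e-300)
    if (abs(sig$sigma[length(z_m)]) > 1e-6 * scale) {
      warning(sprintf(
        "profile is not neutral: residual field %.3g C m^-2 at the boundary",
        sig$sigma[length(z_m)]))
    }
  }
  phi <- -as.numeric(pracma::cumtrapz(z_m, sig$sigma)) / .const$eps0
  n <- length(phi)
  bulk <- seq.int(max(1L, n - ceiling(bulk_frac * n) + 1L), n)
  data.frame(z_A = profile$z_A, phi = phi - mean(phi[bulk]))
}

#' Grahame equation: surface charge from surface potential
#'
#' `sigma = sqrt(8*eps_r*eps0*kB*T*n0) * sinh(e*phi/(2*kB*T))` for a 1:1
#' electrolyte; the exact inverse of [gc_potential()].
#'
#' @param phi Potential in V (vectorised).
#' @param gc A [gc_params()].
#' @return Charge density in C m^-2.
#' @export
grahame_sigma <- function(phi, gc = gc_params()) {
  .sigma_star(gc) *
    sinh(.const$e * phi / (2 * .const$kB * gc$temperature))
}

#' Fit an apparent interfacial dielectric constant via the Grahame equation
#'
#' Least squares over `eps_r` of `sigma(z) - grahame_sigma(phi(z); eps_r)`
#' for z values in a window near the phosphate plane. `phi` should come
#' from [poisson_potential()] of the full (all-components) profile and
#' `sigma` from [integrate_charge()] of the membrane-plus-ions selection
#' (water orientation is what the apparent dielectric constant absorbs;
#' see the package vignette).
#'
#' @param potential Data frame from [poisson_potential()] (`z_A`, `phi`).
#' @param sigma Data frame from [integrate_charge()] (`z_A`, `sigma`).
#' @param window Length-2 z interval in Angstrom (>= 3 grid points).
#' @param c_elec 1:1 electrolyte concentration in mol L^-1 (default the
#'   simulation salt, 0.15 M).
#' @param temperature Temperature in K (default the simulation value).
#' @param eps_range Search interval for `eps_r`.
#' @return Object of class `"grahame_fit"`: `eps_app`, `window`,
#'   per-z `residuals`, `n`.
#' @export
grahame_fit <- function(potential, sigma, window, c_elec = 0.15,
                        temperature = 303.15, eps_range = c(1, 1000)) {
  stopifnot(length(window) == 2, all(potential$z_A == sigma$z_A))
  sel <- potential$z_A >= window[1] & potential$z_A <= window[2]
  if (sum(sel) < 3) {
    stop("z window must contain >= 3 grid points inside the grid",
         call. = FALSE)
  }
  phi <- potential$phi[sel]
  sig <- sigma$sigma[sel]
  if (max(abs(phi)) < 1e-9 && max(abs(sig)) < 1e-12) {
    stop("degenerate fit: potential and charge are both ~ 0 in the window",
         call. = FALSE)
  }
  ssr <- function(log_eps) {
    gce <- gc_params(temperature, c_elec, exp(log_eps))
    sum((sig - grahame_sigma(phi, gce))^2)
  }
  opt <- stats::optimize(ssr, log(eps_range), tol = 1e-10)
  eps_app <- exp(opt$minimum)
  gce <- gc_params(temperature, c_elec, eps_app)
  structure(list(eps_app = eps_app, window = window,
                 residuals = sig - grahame_sigma(phi, gce),
                 n = sum(sel), gc = gce, ssr = opt$objective),
            class = "grahame_fit")
}

#' @export
print.grahame_fit <- function(x, ...) {
  cat(sprintf(
    "Grahame-equation dielectric fit: eps_app = %.3g (z in [%g, %g] A, %d points)\n",
    x$eps_app, x$window[1], x$window[2], x$n))
  cat(sprintf("  RMS residual: %.3g C m^-2 at %g M, %g K\n",
              sqrt(x$ssr / x$n), x$gc$c_elec, x$gc$temperature))
  invisible(x)
}

#' @export
coef.grahame_fit <- function(object, ...) c(eps_app = object$eps_app)

#' @export
residuals.grahame_fit <- function(object, ...) object$residuals

#' Construct a binding geometry
#'
#' Representative sidechain atoms (CZ for Arg, NZ for Lys), lipid
#' phosphorus coordinates, and the orthorhombic box.
#'
#' @param sidechains Data frame with columns `peptide` (id), `type`
#'   (`"ARG"` or `"LYS"`), `x`, `y`, `z` (Angstrom).
#' @param phosphorus Data frame with columns `x`, `y`, `z`.
#' @param box Length-3 box dimensions in Angstrom.
#' @param cutoffs Named numeric binding cutoffs in Angstrom (first RDF
#'   peak; defaults 5.5 for ARG, 4.5 for LYS).
#' @return List of class `"binding_geometry"`.
#' @export
binding_geometry <- function(sidechains, phosphorus, box,
                             cutoffs = c(ARG = 5.5, LYS = 4.5)) {
  stopifnot(all(c("peptide", "type", "x", "y", "z") %in% names(sidechains)),
            all(c("x", "y", "z") %in% names(phosphorus)),
            length(box) == 3, all(box > 0), all(cutoffs > 0))
  if (!all(sidechains$type %in% names(cutoffs))) {
    stop("sidechain type without a cutoff", call. = FALSE)
  }
  structure(list(sidechains = sidechains, phosphorus = phosphorus,
                 box = box, cutoffs = cutoffs),
            class = "binding_geometry")
}

# minimum-image distance matrix between two coordinate sets (orthorhombic)
.min_image_dist <- function(a, b, box) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dx <- outer(a[[k]], b[[k]], "-")
    dx <- dx - box[k] * round(dx / box[k])
    d2 <- d2 + dx^2
  }
  sqrt(d2)
}

#' Count membrane-bound sidechains per peptide
#'
#' A sidechain is bound iff the minimum-image distance from its
#' representative atom to any lipid phosphorus is less than or equal to
#' the cutoff for its residue type (boundary inclusive). A peptide is
#' bound iff at least one of its sidechains is bound.
#'
#' @param geom A [binding_geometry()].
#' @param max_count Upper bin of the count histogram (default 8, the
#'   octapeptide sidechain count).
#' @return List with `per_peptide` (data frame `peptide`, `n_bound`),
#'   `histogram` (counts over 0..`max_count`), `n_bound_peptides`,
#'   `mean_bound` (mean sidechain count among bound peptides, `NA` if
#'   none).
#' @export
bound_monomers <- function(geom, max_count = 8) {
  sc <- geom$sidechains
  if (nrow(sc) == 0) {
    return(list(per_peptide = data.frame(peptide = integer(),
                                         n_bound = integer()),
                histogram = stats::setNames(integer(max_count + 1),
                                            0:max_count),
                n_bound_peptides = 0L, mean_bound = NA_real_))
  }
  if (anyNA(sc$peptide)) stop("missing peptide membership", call. = FALSE)
  d <- .min_image_dist(sc[c("x", "y", "z")], geom$phosphorus[c("x", "y", "z")],
                       geom$box)
  mind <- apply(d, 1, min)
  bound <- mind <= geom$cutoffs[sc$type]
  per <- aggregate(bound, by = list(peptide = sc$peptide), sum)
  names(per)[2] <- "n_bound"
  hist <- table(factor(per$n_bound, levels = 0:max_count))
  nb <- sum(per$n_bound >= 1)
  list(per_peptide = per, histogram = hist, n_bound_peptides = nb,
       mean_bound = if (nb) mean(per$n_bound[per$n_bound >= 1]) else
         NA_real_)
}
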