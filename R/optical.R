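# Optical (solvent-free) surface mass from LSPR wavelength shifts, and the
# mass -> coverage -> charge accounting that follows from it.

#' de Feijter optical surface mass density
#'
#' Converts the LSPR extinction-maximum shift to solvent-free areal mass:
#' `mass = (dlambda/S) * d / (dndc * (1 - exp(-d/L)))`, the de Feijter
#' relation combined with a single-exponential evanescent-field decay of
#' length `L`. When the adlayer thickness `d` is unknown (`d = NULL`) the
#' thin-film limit `mass = dlambda * L / (S * dndc)` is used, which the
#' full form approaches to first order for `d << L`.
#'
#' @param dlambda Wavelength shift in nm (vectorised).
#' @param params An [optical_params()].
#' @param noise Baseline noise level in nm; shifts below `-noise` are
#'   flagged with a warning (apparent desorption below baseline).
#' @return Optical surface mass density in ng cm^-2.
#' @export
#' @examples
#' defeijter_mass(0.5, optical_params(S = 110, L = 20, dndc = 0.182, d = 2))
defeijter_mass <- function(dlambda, params = optical_params(), noise = 0) {
  if (any(dlambda < -noise)) {
    warning("negative wavelength shift beyond noise: desorption below baseline")
  }
  geom <- if (is.null(params$d)) params$L else
    params$d / (1 - exp(-params$d / params$L))
  # (nm/RIU)/(cm^3 g^-1) * nm = 1e-7 g cm^-2 = 100 ng cm^-2
  100 * (dlambda / params$S) * geom / params$dndc
}

#' Hydration (dynamically coupled water) of an adlayer
#'
#' Acoustic mass counts analyte plus dynamically coupled solvent; optical
#' mass counts analyte only. Their difference, as a percentage of the
#' acoustic mass, is the water content of the film.
#'
#' @param acoustic Acoustic surface mass density in ng cm^-2 (> 0).
#' @param optical Optical surface mass density in ng cm^-2.
#' @return Percent hydration; values outside `[0, 100]` (optical mass
#'   exceeding acoustic) are returned as computed with a warning.
#' @export
#' @examples
#' water_content(210, 13)  # ~94 %
water_content <- function(acoustic, optical) {
  if (any(acoustic <= 0)) {
    stop("acoustic mass must be > 0", call. = FALSE)
  }
  pct <- 100 * (acoustic - optical) / acoustic
  if (any(pct < 0 | pct > 100)) {
    warning("water content outside [0, 100]%: optical/acoustic masses inconsistent")
  }
  pct
}

#' Molecular surface coverage from optical mass
#'
#' @param optical Optical surface mass density in ng cm^-2 (>= 0).
#' @param peptide A [peptide_descriptor()].
#' @return Coverage in molecules cm^-2.
#' @export
#' @examples
#' molecular_coverage(5, peptide_descriptor("LYS8"))  # ~2.9e12
molecular_coverage <- function(optical, peptide) {
  stopifnot(all(optical >= 0))
  optical * 1e-9 * .const$N_A / peptide$molar_mass
}

#' Surface charge density assuming full ionization
#'
#' Charge density the adsorbed peptides would add if every ionizable
#' sidechain carried its charge (eight-fold for the octapeptides).
#'
#' @param coverage Molecules cm^-2.
#' @param z_max Charges per molecule (elementary charges).
#' @return Charge density in C m^-2.
#' @export
full_ionization_charge_density <- function(coverage, z_max = 8) {
  stopifnot(all(coverage >= 0), z_max >= 0)
  coverage * 1e4 * z_max * .const$e
}

#' Fractional surface occupancy of the bilayer
#'
#' Area fraction covered assuming the molecules lie down individually with
#' a fixed per-molecule footprint.
#'
#' @param coverage Molecules cm^-2.
#' @param footprint Per-molecule footprint in nm^2.
#' @return Percent of the bilayer area; values above 100 are returned with
#'   a warning.
#' @export
surface_occupancy <- function(coverage, footprint) {
  stopifnot(footprint > 0)
  pct <- 100 * coverage * footprint * 1e-14  # nm^2 -> cm^2
  if (any(pct > 100)) warning("occupancy exceeds 100%")
  pct
}
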