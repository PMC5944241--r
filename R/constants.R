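# Physical constants (CODATA 2018, SI units).
.const <- list(
  e    = 1.602176634e-19,   # elementary charge [C]
  kB   = 1.380649e-23,      # Boltzmann constant [J K-1]
  eps0 = 8.8541878128e-12,  # vacuum permittivity [F m-1]
  N_A  = 6.02214076e23,     # Avogadro number [mol-1]
  R    = 8.314462618        # molar gas constant [J mol-1 K-1]
)

# Average residue masses [g mol-1] of the 20 standard amino acids
# (monomer mass minus one water); peptide mass = sum(residues) + H2O.
.residue_mass <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)
.water_mass <- 18.0153

#' Quartz sensor description
#'
#' Fundamental frequency and Sauerbrey mass-sensitivity constant of the
#' AT-cut quartz crystal. The default is the 4.95 MHz sensor with
#' C = 18 ng cm^-2 Hz^-1.
#'
#' @param f1 Fundamental resonance frequency in Hz.
#' @param C Mass sensitivity constant in ng cm^-2 Hz^-1.
#' @return A list of class `"quartz_sensor"`.
#' @export
quartz_sensor <- function(f1 = 4.95e6, C = 18) {
  stopifnot(is.numeric(f1), f1 > 0, is.numeric(C), C > 0)
  structure(list(f1 = f1, C = C), class = "quartz_sensor")
}

#' Bulk Newtonian fluid above the sensor
#'
#' @param density Fluid density in kg m^-3 (default: water, 1000).
#' @param viscosity Dynamic viscosity in kg m^-1 s^-1 (default 0.001).
#' @return A list of class `"bulk_fluid"`.
#' @export
bulk_fluid <- function(density = 1000, viscosity = 0.001) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity),
            class = "bulk_fluid")
}

#' Viscoelastic (Kelvin-Voigt) adlayer parameters
#'
#' @param h Film thickness in m.
#' @param rho Film density in kg m^-3.
#' @param eta Film shear viscosity in kg m^-1 s^-1.
#' @param mu Film shear elastic modulus in Pa.
#' @return A list of class `"viscoelastic_layer"`. The acoustic areal mass
#'   is `rho * h` (kg m^-2); see [layer_mass()] for the value in ng cm^-2.
#' @export
viscoelastic_layer <- function(h, rho, eta, mu) {
  if (any(c(h, rho, eta, mu) <= 0)) {
    stop("all Kelvin-Voigt layer parameters must be > 0", call. = FALSE)
  }
  structure(list(h = h, rho = rho, eta = eta, mu = mu),
            class = "viscoelastic_layer")
}

#' Acoustic areal mass of a viscoelastic layer in ng cm^-2
#'
#' @param layer A [viscoelastic_layer()].
#' @return Areal mass `rho * h` converted from kg m^-2 to ng cm^-2.
#' @export
layer_mass <- function(layer) {
  layer$rho * layer$h * 1e8  # kg m^-2 -> ng cm^-2
}

#' Gouy-Chapman electrolyte parameters
#'
#' Temperature, 1:1 electrolyte concentration and relative permittivity used
#' in the diffuse-double-layer expressions. The SHG experiments use 0.1 M
#' total electrolyte at room temperature; the simulation analysis uses
#' 0.15 M salt at 303.15 K.
#'
#' @param temperature Absolute temperature in K.
#' @param c_elec 1:1 electrolyte concentration in mol L^-1.
#' @param eps_r Relative permittivity of the medium (dimensionless).
#' @return A list of class `"gc_params"`.
#' @export
gc_params <- function(temperature = 298.15, c_elec = 0.1, eps_r = 78.2) {
  stopifnot(temperature > 0, c_elec > 0, eps_r > 0)
  structure(list(temperature = temperature, c_elec = c_elec, eps_r = eps_r),
            class = "gc_params")
}

#' LSPR optical parameters for the de Feijter conversion
#'
#' @param S Refractive-index sensitivity in nm per refractive-index unit,
#'   measured in the presence of the supported bilayer.
#' @param L Evanescent-field decay length in nm.
#' @param dndc Refractive-index increment of the analyte in cm^3 g^-1
#'   (default 0.182, the standard protein value).
#' @param d Adlayer thickness in nm, or `NULL` to use the thin-film limit
#'   `d << L`.
#' @return A list of class `"optical_params"`.
#' @export
optical_params <- function(S = 110, L = 20, dndc = 0.182, d = NULL) {
  stopifnot(S > 0, L > 0, dndc > 0, is.null(d) || d > 0)
  structure(list(S = S, L = L, dndc = dndc, d = d), class = "optical_params")
}

#' Peptide descriptor: molar mass and maximum charge from sequence
#'
#' Molar mass is computed from average residue masses plus one water;
#' the maximum charge counts cationic sidechains (Lys, Arg). Built-in
#' shortcuts `"LYS8"` ("KKKKKKKK", 1043.4 g mol^-1) and `"ARG8"`
#' ("RRRRRRRR", 1267.5 g mol^-1) name the two octapeptides studied.
#'
#' @param sequence One-letter residue string, or `"LYS8"` / `"ARG8"`.
#' @param molar_mass Optional override of the computed molar mass
#'   (g mol^-1), e.g. for salt forms.
#' @param z_max Optional override of the maximum charge (elementary
#'   charges).
#' @return A list of class `"peptide_descriptor"` with `sequence`,
#'   `molar_mass` and `z_max`.
#' @export
#' @examples
#' peptide_descriptor("LYS8")$molar_mass  # 1043.4
peptide_descriptor <- function(sequence, molar_mass = NULL, z_max = NULL) {
  seq_up <- toupper(sequence)
  if (seq_up == "LYS8") seq_up <- strrep("K", 8)
  if (seq_up == "ARG8") seq_up <- strrep("R", 8)
  res <- strsplit(seq_up, "")[[1]]
  if (!all(res %in% names(.residue_mass))) {
    stop("unknown residue code(s): ",
         paste(setdiff(res, names(.residue_mass)), collapse = ", "),
         call. = FALSE)
  }
  M <- if (is.null(molar_mass)) {
    sum(.residue_mass[res]) + .water_mass
  } else molar_mass
  z <- if (is.null(z_max)) sum(res %in% c("K", "R")) else z_max
  stopifnot(M > 0, z >= 0)
  structure(list(sequence = seq_up, molar_mass = M, z_max = z),
            class = "peptide_descriptor")
}
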