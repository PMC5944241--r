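# Delimited-text readers/writers for every file dialect, structured
# configuration with unknown-key rejection, and the end-to-end
# charge-counting pipeline driver.
#
# All files are whitespace/tab-delimited with '#' header lines of the
# form "# key: value" carrying units and dialect flags. Canonical units:
# concentrations in mol L^-1, masses in ng cm^-2, charge densities in
# C m^-2, z in Angstrom, dissipation shifts stored as absolute values.

.read_header <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
  }
  kv
}

.write_table <- function(df, file, header = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  for (k in names(header)) {
    writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.read_table <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read / write QCM-D harmonic traces
#'
#' Columns `time_s`, `harmonic`, `df_Hz`, `dD_e6`. Header keys:
#' `f1_Hz` (sensor fundamental), `df_dialect` (`raw` or `normalized`,
#' i.e. whether `df_Hz` was pre-divided by the harmonic), `dD_units`
#' (`1e-6`, the default, or `abs`). The returned trace is canonical:
#' raw `df_Hz` and absolute `dD`.
#'
#' @param file Path to the trace file.
#' @return Data frame `time_s`, `harmonic`, `df_Hz`, `dD` with attribute
#'   `"f1_Hz"` when declared.
#' @export
read_qcmd <- function(file) {
  kv <- .read_header(file)
  df <- .read_table(file)
  stopifnot(all(c("time_s", "harmonic", "df_Hz") %in% names(df)))
  if (identical(kv$df_dialect, "normalized")) {
    df$df_Hz <- df$df_Hz * df$harmonic
  }
  dD_col <- intersect(c("dD_e6", "dD"), names(df))[1]
  scale <- if (identical(kv$dD_units, "abs")) 1 else 1e-6
  df$dD <- df[[dD_col]] * scale
  out <- df[c("time_s", "harmonic", "df_Hz", "dD")]
  if (!is.null(kv$f1_Hz)) attr(out, "f1_Hz") <- as.numeric(kv$f1_Hz)
  out
}

#' @param trace Canonical trace data frame (`time_s`, `harmonic`,
#'   `df_Hz`, `dD`).
#' @param sensor A [quartz_sensor()] recorded in the header.
#' @rdname read_qcmd
#' @export
write_qcmd <- function(trace, file, sensor = quartz_sensor()) {
  out <- data.frame(time_s = trace$time_s, harmonic = trace$harmonic,
                    df_Hz = trace$df_Hz, dD_e6 = trace$dD * 1e6)
  .write_table(out, file, list(f1_Hz = sensor$f1, df_dialect = "raw",
                               dD_units = "1e-6"))
  invisible(file)
}

#' Read / write LSPR wavelength-shift traces
#'
#' Columns `time_s`, `dlambda_nm`.
#' @param file Path.
#' @return Data frame `time_s`, `dlambda_nm`.
#' @export
read_lspr <- function(file) {
  df <- .read_table(file)
  stopifnot(all(c("time_s", "dlambda_nm") %in% names(df)))
  df[c("time_s", "dlambda_nm")]
}

#' @param trace Data frame `time_s`, `dlambda_nm`.
#' @rdname read_lspr
#' @export
write_lspr <- function(trace, file) {
  .write_table(trace[c("time_s", "dlambda_nm")], file)
  invisible(file)
}

#' Read / write SHG isotherms
#'
#' Columns `conc_M`, `E_norm`, `sigma_E`, optional `extrapolated` (0/1).
#' Header key `signal: efield` (default) or `signal: intensity`; for
#' intensity input, `E_norm = sqrt(I/I0)` is applied (with uncertainty
#' propagated) on read.
#'
#' @param file Path.
#' @return An [isotherm_data()].
#' @export
read_isotherm <- function(file) {
  kv <- .read_header(file)
  df <- .read_table(file)
  stopifnot(all(c("conc_M", "E_norm") %in% names(df)))
  if (is.null(df$sigma_E)) df$sigma_E <- 0.02 * df$E_norm
  if (identical(kv$signal, "intensity")) {
    df$sigma_E <- df$sigma_E / (2 * sqrt(df$E_norm))
    df$E_norm <- sqrt(df$E_norm)
  }
  ex <- if (is.null(df$extrapolated)) FALSE else df$extrapolated == 1
  isotherm_data(df$conc_M, df$E_norm, df$sigma_E, ex)
}

#' @param iso An [isotherm_data()].
#' @rdname read_isotherm
#' @export
write_isotherm <- function(iso, file) {
  out <- data.frame(conc_M = iso$conc_M, E_norm = iso$E_norm,
                    sigma_E = iso$sigma_E,
                    extrapolated = as.integer(iso$extrapolated))
  .write_table(out, file, list(signal = "efield"))
  invisible(file)
}

#' Read / write charge-density profiles
#'
#' Column `z_A` plus one `rho_<component>` column per component. Header
#' keys: `rho_units` (`C_m3` or `e_A3`) and `area_A2`.
#'
#' @param file Path.
#' @return A [charge_profile()].
#' @export
read_charge_profile <- function(file) {
  kv <- .read_header(file)
  df <- .read_table(file)
  stopifnot("z_A" %in% names(df))
  comps <- grep("^rho_", names(df), value = TRUE)
  rho <- df[comps]
  names(rho) <- sub("^rho_", "", comps)
  charge_profile(df$z_A, rho,
                 units = if (is.null(kv$rho_units)) "C_m3" else
                   kv$rho_units,
                 area = if (is.null(kv$area_A2) ||
                            identical(kv$area_A2, "NA")) NA_real_ else
                   as.numeric(kv$area_A2))
}

#' @param profile A [charge_profile()].
#' @rdname read_charge_profile
#' @export
write_charge_profile <- function(profile, file) {
  .write_table(as.data.frame(profile), file,
               list(rho_units = "C_m3",
                    area_A2 = attr(profile, "area_A2")))
  invisible(file)
}

#' Read / write binding geometries
#'
#' Atom table with columns `role` (`P` for lipid phosphorus, or the
#' residue type `ARG`/`LYS` of a representative sidechain atom),
#' `peptide` (id; 0 for phosphorus), `x`, `y`, `z`. Header keys
#' `box_A: Lx Ly Lz` and optional `cutoff_ARG` / `cutoff_LYS`.
#'
#' @param file Path.
#' @return A [binding_geometry()].
#' @export
read_binding_geometry <- function(file) {
  kv <- .read_header(file)
  df <- .read_table(file)
  stopifnot(all(c("role", "peptide", "x", "y", "z") %in% names(df)),
            !is.null(kv$box_A))
  box <- as.numeric(strsplit(kv$box_A, "\\s+")[[1]])
  cutoffs <- c(
    ARG = if (is.null(kv$cutoff_ARG)) 5.5 else as.numeric(kv$cutoff_ARG),
    LYS = if (is.null(kv$cutoff_LYS)) 4.5 else as.numeric(kv$cutoff_LYS))
  P <- df[df$role == "P", c("x", "y", "z")]
  sc <- df[df$role != "P", c("peptide", "role", "x", "y", "z")]
  names(sc)[2] <- "type"
  binding_geometry(sc, P, box, cutoffs)
}

#' @param geom A [binding_geometry()].
#' @rdname read_binding_geometry
#' @export
write_binding_geometry <- function(geom, file) {
  sc <- geom$sidechains
  atoms <- rbind(
    data.frame(role = "P", peptide = 0, x = geom$phosphorus$x,
               y = geom$phosphorus$y, z = geom$phosphorus$z),
    data.frame(role = sc$type, peptide = sc$peptide, x = sc$x, y = sc$y,
               z = sc$z))
  .write_table(atoms, file, list(
    box_A = paste(geom$box, collapse = " "),
    cutoff_ARG = geom$cutoffs[["ARG"]],
    cutoff_LYS = geom$cutoffs[["LYS"]]))
  invisible(file)
}

# --- configuration ---------------------------------------------------------

.config_defaults <- function() {
  list(
    sensor = list(f1 = 4.95e6, C = 18),
    fluid = list(density = 1000, viscosity = 0.001),
    rho_film = 1050,
    optics = list(S = 110, L = 20, dndc = 0.182, d = NULL),
    gc = list(temperature = 298.15, c_elec = 0.1, eps_r = 78.2),
    peptide = "LYS8",
    sigma0 = -0.1,
    fix_B = NULL,
    footprint_nm2 = c(LYS8 = 4.0, ARG8 = 4.7),
    c_extrap = 0.1, k_extrap = 3,
    sensitivity = 0.10,
    seed = 1
  )
}

#' Load an analysis configuration
#'
#' YAML configuration merged over the package defaults; keys absent from
#' the default schema are rejected.
#'
#' @param file YAML file path, or `NULL` for the defaults.
#' @param overrides Named list applied after the file.
#' @return Configuration list of class `"analysis_config"`.
#' @export
analysis_config <- function(file = NULL, overrides = list()) {
  cfg <- .config_defaults()
  apply_over <- function(cfg, new, where = "") {
    bad <- setdiff(names(new), names(cfg))
    if (length(bad)) {
      stop("unknown config key(s): ",
           paste0(where, bad, collapse = ", "), call. = FALSE)
    }
    for (k in names(new)) {
      if (is.list(new[[k]]) && is.list(cfg[[k]])) {
        cfg[[k]] <- apply_over(cfg[[k]], new[[k]],
                               paste0(where, k, "."))
      } else cfg[[k]] <- new[[k]]
    }
    cfg
  }
  if (!is.null(file)) cfg <- apply_over(cfg, yaml::read_yaml(file))
  cfg <- apply_over(cfg, overrides)
  class(cfg) <- "analysis_config"
  cfg
}

#' Hash of the semantic content of a configuration
#'
#' @param config An [analysis_config()].
#' @return MD5 hex string; changes iff any semantic field changes.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))], control = "all"), tmp)
  unname(tools::md5sum(tmp))
}

# --- pipeline --------------------------------------------------------------

#' Run the end-to-end charge-counting pipeline
#'
#' Composes the analysis stages into the summary-table quantity set:
#' Kelvin-Voigt acoustic mass from the QCM-D trace, de Feijter optical
#' mass from the LSPR trace, water content, molecular coverage, surface
#' occupancy, full-ionization charge density, Hill/Gouy-Chapman isotherm
#' fit (with extrapolated saturation point and sensitivity scan),
#' adsorption free energy and percent ionization.
#'
#' @param config An [analysis_config()].
#' @param qcmd Canonical QCM-D trace (see [read_qcmd()]) or file path.
#' @param lspr LSPR trace (see [read_lspr()]) or file path.
#' @param isotherm An [isotherm_data()] or file path.
#' @param qcmd_window,lspr_window Plateau time windows (s); default the
#'   last 10% of each trace.
#' @return List of class `"charge_report"` with every derived quantity
#'   plus provenance (config hash, seed).
#' @export
run_charge_pipeline <- function(config = analysis_config(), qcmd, lspr,
                                isotherm, qcmd_window = NULL,
                                lspr_window = NULL) {
  if (missing(qcmd) || missing(lspr) || missing(isotherm)) {
    stop("qcmd, lspr and isotherm inputs are all required", call. = FALSE)
  }
  if (is.character(qcmd)) qcmd <- read_qcmd(qcmd)
  if (is.character(lspr)) lspr <- read_lspr(lspr)
  if (is.character(isotherm)) isotherm <- read_isotherm(isotherm)

  sensor <- quartz_sensor(config$sensor$f1, config$sensor$C)
  fluid <- bulk_fluid(config$fluid$density, config$fluid$viscosity)
  optics <- do.call(optical_params, config$optics)
  gc <- do.call(gc_params, config$gc)
  pep <- peptide_descriptor(config$peptide)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (is.null(qcmd_window)) {
    qcmd_window <- stats::quantile(qcmd$time_s, c(0.9, 1))
  }
  if (is.null(lspr_window)) {
    lspr_window <- stats::quantile(lspr$time_s, c(0.9, 1))
  }

  kv <- stage("acoustic_mass", kv_fit(qcmd, window = qcmd_window,
                                      rho_film = config$rho_film,
                                      fluid = fluid, sensor = sensor))
  rig <- stage("rigidity", rigidity_ratio(qcmd, window = qcmd_window))

  lsel <- lspr$time_s >= lspr_window[1] & lspr$time_s <= lspr_window[2]
  opt_mass <- stage("optical_mass",
                    mean(defeijter_mass(lspr$dlambda_nm[lsel], optics)))

  water <- stage("water_content", water_content(kv$mass, opt_mass))
  coverage <- stage("coverage", molecular_coverage(opt_mass, pep))
  sigma_full <- stage("full_ionization",
                      full_ionization_charge_density(coverage, pep$z_max))
  fp <- config$footprint_nm2
  fp1 <- if (toupper(config$peptide) %in% names(fp))
    fp[[toupper(config$peptide)]] else fp[[1]]
  occupancy <- stage("occupancy", surface_occupancy(coverage, fp1))

  if (!any(isotherm$extrapolated)) {
    isotherm <- stage("extrapolation",
                      augment_extrapolated(isotherm, config$c_extrap,
                                           config$k_extrap))
  }
  fit <- stage("isotherm_fit", hillgc(isotherm, sigma0 = config$sigma0,
                                      gc = gc, fix_B = config$fix_B))
  sens <- stage("sensitivity", sensitivity_scan(fit, config$sensitivity))
  cf <- coef(fit)
  dG <- adsorption_free_energy(cf[["K_ads"]], gc$temperature)
  ion <- percent_ionization(cf[["dsigma"]], sigma_full)

  structure(list(
    peptide = pep$sequence,
    mass_acoustic = kv$mass, mass_acoustic_se = kv$mass_se,
    rigidity_ratio = rig$ratio, rigid = rig$rigid,
    mass_optical = opt_mass,
    water_content = water,
    coverage = coverage, occupancy = occupancy,
    sigma_full = sigma_full,
    K_ads = cf[["K_ads"]],
    K_se = sqrt(fit$vcov["K_ads", "K_ads"]),
    n = cf[["n"]], n_se = sqrt(fit$vcov["n", "n"]),
    dsigma = cf[["dsigma"]],
    dsigma_se = sqrt(fit$vcov["dsigma", "dsigma"]),
    dsigma_range = sens$dsigma_range, K_range = sens$K_range,
    dG = dG, percent_ionization = ion,
    fit = fit, kv = kv,
    provenance = list(config_hash = config_hash(config),
                      seed = config$seed)
  ), class = "charge_report")
}

#' @export
print.charge_report <- function(x, ...) {
  cat("Charge-counting report:", x$peptide, "\n")
  cat(sprintf("  acoustic mass   : %.3g ng cm^-2 (Kelvin-Voigt)\n",
              x$mass_acoustic))
  cat(sprintf("  rigidity ratio  : %.3g Hz^-1 (%s)\n", x$rigidity_ratio,
              if (x$rigid) "rigid" else "viscoelastic"))
  cat(sprintf("  optical mass    : %.3g ng cm^-2 (de Feijter)\n",
              x$mass_optical))
  cat(sprintf("  water content   : %.1f %%\n", x$water_content))
  cat(sprintf("  coverage        : %.3g molecules cm^-2 (%.1f%% occupancy)\n",
              x$coverage, x$occupancy))
  cat(sprintf("  K_ads           : %.3g M^-1; n = %.2f\n", x$K_ads, x$n))
  cat(sprintf("  dG_ads          : %.3g kJ mol^-1 (55.5 M reference)\n",
              x$dG))
  cat(sprintf("  dsigma (SHG)    : %.3g C m^-2 [%.3g, %.3g]\n",
              x$dsigma, x$dsigma_range[1], x$dsigma_range[2]))
  cat(sprintf("  sigma full-ion. : %.3g C m^-2\n", x$sigma_full))
  ion_txt <- if (x$percent_ionization >= 100 ||
                 abs(x$percent_ionization - 100) <=
                 100 * x$dsigma_se / max(x$sigma_full, 1e-12))
    "~100" else sprintf("%.0f", x$percent_ionization)
  cat(sprintf("  %% ionization    : %s\n", ion_txt))
  cat(sprintf("  provenance      : config %s, seed %d\n",
              substr(x$provenance$config_hash, 1, 8),
              x$provenance$seed))
  invisible(x)
}

#' Write a machine-readable charge report
#'
#' Key/value JSON with every numeric quantity and provenance; rereading
#' the same inputs with the same configuration yields a byte-identical
#' file.
#'
#' @param report A `"charge_report"`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_charge_report <- function(report, file) {
  keep <- c("peptide", "mass_acoustic", "mass_acoustic_se",
            "rigidity_ratio", "rigid", "mass_optical", "water_content",
            "coverage", "occupancy", "sigma_full", "K_ads", "K_se", "n",
            "n_se", "dsigma", "dsigma_se", "dsigma_range", "K_range",
            "dG", "percent_ionization", "provenance")
  jsonlite::write_json(report[keep], file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
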