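Package: pepcharge
Title: Counting Charges on Membrane-Bound Cationic Octapeptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of cationic octapeptide (Lys8, Arg8)
    adsorption to supported lipid bilayers. Converts QCM-D
    frequency/dissipation responses to acoustic surface mass via the
    Sauerbrey relation or a Kelvin-Voigt viscoelastic fit, converts LSPR
    wavelength shifts to optical (solvent-free) mass via the de Feijter
    relation, fits surface-potential-sensitive SHG adsorption isotherms
    with a combined Hill/Gouy-Chapman model to estimate binding constants
    and peptide-added surface charge density, reconciles charge per
    peptide, and post-processes simulation-derived charge-density
    profiles (Poisson integration, Grahame-equation fits for an apparent
    interfacial dielectric constant, bound-sidechain counting). A
    synthetic-data module generates every input class with known ground
    truth so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
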