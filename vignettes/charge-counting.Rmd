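---
title: "Counting charges on membrane-bound cationic octapeptides"
author: "pepcharge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting charges on membrane-bound cationic octapeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepcharge)
```

# The problem

Cationic oligopeptides such as octalysine (Lys8) and octaarginine (Arg8)
bind to anionic lipid membranes, and the number of charges they carry
*while bound* controls the electrostatics of the interface. `pepcharge`
implements the quantitative chain that brackets that number from three
label-free measurements plus simulation post-processing:

1. **Acoustic mass** (QCM-D): how much peptide *plus dynamically coupled
   water* is on the surface.
2. **Optical mass** (LSPR): how much peptide alone is on the surface,
   hence the molecular coverage and the charge density the adlayer would
   carry if fully ionized.
3. **SHG isotherms**: how much charge the adlayer actually adds, from the
   surface-potential dependence of the second-harmonic response.
4. **Charge-density profiles** from atomistic simulation: whether the
   mean-field (Gouy–Chapman) mapping between potential and charge used in
   step 3 is trustworthy at a lipid–water interface, summarized by an
   apparent interfacial dielectric constant.

The ratio of (3) to (2) is the percent ionization of the bound peptides.

# Models and conventions

## Acoustic mass: Sauerbrey and Kelvin–Voigt

For rigid films the Sauerbrey relation applies per odd harmonic $\nu$:
$\Delta\Gamma = -C\,\Delta f_\nu/\nu$ with $C = 18$ ng cm$^{-2}$ Hz$^{-1}$
at $f_1 = 4.95$ MHz. Films are classified rigid when
$\Delta D_\nu/(-\Delta f_\nu/\nu) < 0.4\times10^{-6}$ Hz$^{-1}$; the
classifier flags borderline ratios (within 25% of the threshold) rather
than silently deciding.

Dissipative films are inverted with the standard small-load, first-order
expressions for one Kelvin–Voigt film (thickness $h$, density $\rho$,
shear viscosity $\eta$, shear modulus $\mu$) beneath a semi-infinite
Newtonian liquid; the exact formulas are written out at the head of
`R/acoustic.R`. The quartz areal mass is tied to the Sauerbrey constant
($\rho_q h_q = C f_1$) so the rigid limit reproduces Sauerbrey exactly —
this identity is one of the package's self-checks. Choices the
instrument-side literature leaves open, fixed here:

* **Film density** is not identifiable jointly with thickness; it is
  fixed at 1050 kg m$^{-3}$ (config-overridable), a typical value for a
  highly hydrated biomolecular adlayer. Only the product $\rho h$ (the
  acoustic mass) is reported as a primary result.
* **Joint fit weighting**: frequency residuals are scaled by a noise
  estimate in Hz (default 1), dissipation residuals by one in absolute
  dissipation units (default $10^{-6}$); both should be set from
  baseline-window standard deviations when available.
* The fit runs on log-parameters from a deterministic 18-point start
  grid; non-convergence is flagged on the returned object, never silent.

## Optical mass: de Feijter with evanescent decay

$$\Delta\Gamma = \frac{\Delta\lambda_{max}/S'}
  {\mathrm{d}n/\mathrm{d}C}\cdot
  \frac{d}{1 - e^{-d/L}}$$

with sensitivity $S'$ (nm/RIU, measured in the presence of the bilayer),
decay length $L$, and adlayer thickness $d$. When $d$ is unknown the
thin-film limit $\Delta\Gamma = \Delta\lambda_{max} L/(S'\,
\mathrm{d}n/\mathrm{d}C)$ is the default; it agrees with the full form to
first order in $d/L$. The default refractive-index increment is the
standard protein value 0.182 cm$^3$ g$^{-1}$. Coverage follows as
$\Delta\Gamma N_A/M$; molar masses are computed from average residue
masses (Lys8 1043.4, Arg8 1267.5 g mol$^{-1}$) and are overridable for
salt forms. The occupancy calculation needs a per-molecule footprint;
defaults of 4.0 nm$^2$ (Lys8) and 4.7 nm$^2$ (Arg8) are declared,
back-computed from the reported coverage/occupancy pairs, and should be
replaced by measured values when available.

## SHG isotherms: combined Hill/Gouy–Chapman model

The diffuse-double-layer potential of a plane carrying charge density
$\sigma$ in a 1:1 electrolyte is
$\Phi_0 = (2k_BT/e)\,\mathrm{asinh}(\sigma/\sigma^*)$ with
$\sigma^* = \sqrt{8\varepsilon_r\varepsilon_0k_BTn_0}$. Adsorption
follows a Hill isotherm $\theta = (K_{ads}c)^n/(1+(K_{ads}c)^n)$ and adds
charge $\theta\,\Delta\sigma$ to the initial bilayer charge $\sigma_0$
(fixed at $-0.1$ C m$^{-2}$, the prior estimate for this bilayer on
fused silica). The second-harmonic field is linear in the potential, so
the bare-bilayer-normalized response is

$$E_{norm}(c) = \frac{A + B\,\Phi_0(\sigma_0 + \theta(c)\Delta\sigma)}
  {A + B\,\Phi_0(\sigma_0)}.$$

Conventions and numerical choices:

* Electrolyte 0.1 M total 1:1 salt, $T = 298.15$ K,
  $\varepsilon_r = 78.2$ for the experimental analysis.
* Only $B/A$ is identifiable (the ratio form is invariant to joint
  rescaling), so $A$ is fixed at 1.
* $K_{ads}$ and $n$ are fitted on the log scale; a deterministic
  24-point multi-start grid (signs chosen from the direction of the
  response and the sign of $\Phi_0(\sigma_0)$) guards against the
  multi-modality typical of isotherm fits.
* Saturation is usually not reached experimentally, so one extrapolated
  point at 0.1 M is appended whose value is the mean of the last three
  measured points; `sensitivity_scan()` refits with that value scaled by
  $\pm 10\%$ and reports the resulting parameter ranges.
* Intensity-dialect inputs are converted by $E = \sqrt{I/I_0}$ on read.
* Free energies use $\Delta G = -RT\ln(55.5\,\mathrm{M}\cdot K_{ads})$
  at 298.15 K. This mole-fraction reference is adopted because it is the
  unique convention that reproduces both reported $(K, \Delta G)$ pairs.

### Identifiability of $B$ and $\Delta\sigma$, and the `fix_B` option

With all four parameters free, $B$ and $\Delta\sigma$ trade off along a
ridge: a larger $|B|$ with a smaller $\Delta\sigma$ produces nearly the
same normalized curve, because the data constrain mainly the product of
the response coefficient with the potential change. A local
information analysis at the package's reference conditions (12
log-spaced concentrations, 1% multiplicative noise, extrapolated 0.1 M
point) puts the attainable relative standard error on $\Delta\sigma$
near 90% — consistent with the wide $\pm10\%$-sensitivity ranges this
kind of analysis reports. In the $\chi^{(3)}$ "optical voltmeter"
picture, however, $B$ is an interface response constant that can be
calibrated independently of any one isotherm. `hillgc()` therefore
accepts `fix_B`: when a calibration value is supplied, the three
physical parameters $(K_{ads}, n, \Delta\sigma)$ become well
conditioned (median recovery errors of roughly 10%, 4% and 0.6% over
100 simulated isotherms at 1% noise). The default remains the free
four-parameter fit; its covariance matrix makes the ridge visible
rather than hiding it.

## Interfacial electrostatics from simulation profiles

Charge-density profiles $\rho(z)$ arrive z-binned and
component-resolved (lipid, ions, water, peptide, total). The package
computes

* $\sigma(z) = \int_0^z \rho\,\mathrm{d}z'$ (trapezoid rule, from the
  bilayer center),
* $\phi(z) = -\varepsilon_0^{-1}\int_0^z\!\!\int_0^{z'}\rho$, using the
  *vacuum* permittivity because all charges — including solvent — are
  explicit in $\rho$. The potential is shifted so its bulk average
  (trailing 10% of the grid by default) is zero, making surface values
  directly comparable with Gouy–Chapman; the reference convention is
  declared, not inherited from the data.

`grahame_fit()` then asks what dielectric constant makes the
Grahame equation
$\sigma = \sigma^*(\varepsilon)\sinh(e\phi/2k_BT)$ consistent with the
$(\phi(z), \sigma(z))$ pairs in a window near the phosphate plane
($z \approx 20$ Å; the window bounds are parameters because no canonical
series of $z$ values exists). The convention that makes this
well-posed: **$\sigma$ is the cumulative charge of the non-water
components (lipid + ions + peptide), while $\phi$ comes from the full
profile.** Water's orientational charge is precisely what the *apparent*
dielectric constant absorbs. On the analytic fixture below this
convention recovers the ground-truth $\varepsilon$ exactly; had the
total (water-inclusive) $\sigma$ been used instead, the fitted constant
would collapse to $1/\varepsilon$.

Bound-sidechain counting uses minimum-image distances in the
orthorhombic box from the representative atom (CZ for Arg, NZ for Lys)
to the nearest lipid phosphorus; the first-RDF-peak cutoffs (5.5 Å Arg,
4.5 Å Lys) are taken as given constants, and the boundary is inclusive
("$\le$") — a convention that had to be fixed for exact oracle
comparisons. A peptide counts as bound when at least one sidechain is.

# The synthetic-data generators

Every input class can be generated with known ground truth
(`scenario_spec()` and the `sim_*` functions), so the whole pipeline is
testable without measured data. Defaults are the Arg8 study conditions:
acoustic/optical plateau masses 210/13 ng cm$^{-2}$, $K_{ads} =
1.6\times10^6$ M$^{-1}$, $n = 0.54$, $\Delta\sigma = 0.10$ C m$^{-2}$,
$\sigma_0 = -0.1$ C m$^{-2}$, 0.1 M electrolyte. Values the record does
not state were chosen once as field-typical: exponential-saturation
kinetics with a 300 s time constant, a soft film
($\eta = 1.5\times10^{-3}$ kg m$^{-1}$ s$^{-1}$, $\mu = 10^5$ Pa), an
SHG response coefficient $B = -5$ V$^{-1}$, additive Gaussian noise for
$\Delta f$ (0.2 Hz), $\Delta D$ ($5\times10^{-8}$) and
$\Delta\lambda_{max}$ (0.002 nm), and multiplicative 1% noise for the
SHG E-field (instrument-typical noise structures).

The Gouy–Chapman profile generator builds a lipid charge sheet, the
Boltzmann counter-ion cloud, and the water *bound* (polarization)
charge — a volume term $-(\varepsilon-1)/\varepsilon$ times the ion
charge plus a compensating surface sheet — so that the
vacuum-permittivity Poisson integral of the total reproduces the
analytic Gouy–Chapman potential for the chosen $\varepsilon$.
Numerical details: the ion cloud takes half its contact value in the
surface bin (so the trapezoid rule integrates cleanly across the
discontinuity) and is rescaled by $<10^{-6}$ to make the full profile
integrate to zero exactly.

What the generators do **not** emulate: bilayer-formation transients,
drift, overtone-dependent sensitivity, the mechanistic statistics of
interfacial water orientation (a fixed dipolar sheet pair can be added
to exercise component decomposition, nothing more), or raw SHG photon
counting. Passing tests therefore demonstrate the *estimators* are
correct and well-conditioned under realistic noise — not that every
real-data complication is handled.

# Worked example

```{r example}
spec <- scenario_spec()                       # Arg8 reference conditions
sim <- sim_qcmd_lspr(spec, times = seq(0, 10800, by = 60), seed = 1)
iso <- sim_isotherm(spec, seed = 1)
cfg <- analysis_config(overrides = list(peptide = "ARG8",
                                        fix_B = spec$B))
report <- run_charge_pipeline(cfg, sim$qcmd, sim$lspr, iso,
                              qcmd_window = c(9000, 10800),
                              lspr_window = c(9000, 10800))
report
```

```{r isotherm-fit, fig.width = 5, fig.height = 4}
fit <- hillgc(augment_extrapolated(iso), fix_B = spec$B)
summary(fit)
plot(fit)
```

```{r dielectric}
prof <- sim_gc_profile(sigma0 = -0.1, gc = gc_params(303.15, 0.15, 27))
grahame_fit(poisson_potential(prof),
            integrate_charge(prof, c("lipid", "ions")),
            window = c(20.5, 26))
```

# Problem sizes and determinism

The shipped tests and the acceptance script use: 100 simulated isotherms
of 13 points for the recovery study; QCM-D traces of 181 time points on
three harmonics; 0.1 Å profile grids over 80 Å (801 points); and 50
randomized 5-peptide binding fixtures checked against an explicit
all-pairs, 27-image oracle. All stochastic steps take explicit seeds and
are bit-reproducible.

# Known limitations

* The Kelvin–Voigt inversion is the first-order small-load
  approximation; very thick or very lossy films need the full
  transfer-matrix expressions.
* The free four-parameter isotherm fit is honest about — but cannot
  remove — the $B$–$\Delta\sigma$ ridge; quantitative $\Delta\sigma$
  values need a calibrated $B$ (or an informative prior).
* Percent-ionization values above 100% are physically a statement of
  full ionization combined with mass/charge uncertainty; reports cap
  them at "~100" by convention.
* Phase-matching/coherence-length corrections to the $\chi^{(3)}$
  response, multilayer viscoelastic models, and RDF computation itself
  are out of scope; cutoffs and optical constants enter as
  configuration.
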