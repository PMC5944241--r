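# Acoustic surface mass from QCM-D responses.
#
# Two regimes: rigid adlayers (Sauerbrey relation) and dissipative adlayers
# (Kelvin-Voigt viscoelastic film under a semi-infinite Newtonian liquid,
# small-load first-order expressions of Voinova et al. 1999). With
# omega = 2*pi*nu*f1 and viscous penetration depth
# delta = sqrt(2*eta_l/(rho_l*omega)):
#
#   df_nu = -(1/(2*pi*rho_q*h_q)) * [ eta_l/delta + h*rho*omega
#             - 2*h*(eta_l/delta)^2 * eta*omega^2/(mu^2 + omega^2*eta^2) ]
#   dD_nu =  (1/(2*pi*nu*f1*rho_q*h_q)) * [ 2*eta_l/delta
#             + 2*h*(eta_l/delta)^2 * mu*omega/(mu^2 + omega^2*eta^2) ]
#
# The quartz areal mass rho_q*h_q is tied to the Sauerbrey constant by
# rho_q*h_q = C*f1, so the rigid limit (mu -> inf) reproduces
# df_nu/nu = -rho*h/C exactly.

.check_harmonic <- function(harmonic) {
  if (any(harmonic < 1) || any(harmonic %% 2 != 1)) {
    stop("harmonic must be an odd positive integer", call. = FALSE)
  }
}

# quartz areal mass [kg m-2] from the sensor's Sauerbrey constant
.quartz_areal_mass <- function(sensor) {
  (sensor$C * 1e-8) * sensor$f1  # ng cm-2 Hz-1 -> kg m-2 Hz-1, times f1
}

#' Sauerbrey acoustic surface mass density
#'
#' Converts a harmonic frequency shift to areal mass for a rigid,
#' low-dissipation film: `mass = -C * df / nu`. A negative frequency shift
#' yields positive adsorbed mass.
#'
#' @param df Frequency shift of harmonic `nu` in Hz (vectorised).
#' @param harmonic Odd positive harmonic number.
#' @param sensor A [quartz_sensor()].
#' @return Surface mass density in ng cm^-2.
#' @export
#' @examples
#' sauerbrey_mass(-30, 3)  # 180 ng cm^-2
sauerbrey_mass <- function(df, harmonic, sensor = quartz_sensor()) {
  .check_harmonic(harmonic)
  -sensor$C * df / harmonic
}

#' Rigidity ratio dD/(-df/nu) and film classification
#'
#' The dissipation-to-normalized-frequency ratio discriminates rigid films
#' (Sauerbrey applicable) from viscoelastic ones. Films with a ratio below
#' 0.4e-6 Hz^-1 are classified rigid; ratios within `borderline_frac` of
#' the threshold are flagged borderline rather than silently classified.
#'
#' @param trace Data frame with columns `time_s`, `harmonic`, `df_Hz`, `dD`
#'   (dissipation shift, absolute units).
#' @param window Length-2 numeric time interval (s) to average over;
#'   default the whole trace.
#' @param threshold Classification threshold in Hz^-1.
#' @param borderline_frac Relative band around the threshold flagged as
#'   borderline.
#' @return List with `ratio` (Hz^-1), `rigid` (logical) and `borderline`
#'   (logical).
#' @export
rigidity_ratio <- function(trace, window = NULL, threshold = 0.4e-6,
                           borderline_frac = 0.25) {
  if (is.null(window)) window <- range(trace$time_s)
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (!any(sel)) stop("window contains no samples", call. = FALSE)
  tr <- trace[sel, , drop = FALSE]
  fn <- -tr$df_Hz / tr$harmonic
  if (any(fn == 0)) {
    stop("normalized frequency shift is zero; ratio undefined",
         call. = FALSE)
  }
  ratio <- mean(tr$dD / fn)
  list(ratio = ratio,
       rigid = ratio < threshold,
       borderline = abs(ratio - threshold) < borderline_frac * threshold)
}

#' Kelvin-Voigt forward model for a film under Newtonian liquid
#'
#' Predicts per-harmonic frequency and dissipation shifts of a single
#' viscoelastic film beneath a semi-infinite Newtonian liquid (small-load
#' first-order expressions; see the formulas at the top of the source
#' file). With `reference = "liquid"` (default) the shifts are relative to
#' the liquid-loaded baseline, matching traces baselined before adsorption;
#' `"unloaded"` includes the liquid loading itself.
#'
#' @param layer A [viscoelastic_layer()], or `NULL` for no film.
#' @param fluid A [bulk_fluid()].
#' @param sensor A [quartz_sensor()].
#' @param harmonics Integer vector of odd harmonic numbers.
#' @param reference `"liquid"` or `"unloaded"`.
#' @return Data frame with columns `harmonic`, `df_Hz`, `dD`.
#' @export
kelvin_voigt_forward <- function(layer, fluid = bulk_fluid(),
                                 sensor = quartz_sensor(),
                                 harmonics = c(3, 5, 7, 9, 11),
                                 reference = c("liquid", "unloaded")) {
  reference <- match.arg(reference)
  .check_harmonic(harmonics)
  mq <- .quartz_areal_mass(sensor)
  omega <- 2 * pi * harmonics * sensor$f1
  delta <- sqrt(2 * fluid$viscosity / (fluid$density * omega))
  liq <- fluid$viscosity / delta
  if (is.null(layer)) {
    film_f <- film_D <- 0
  } else {
    denom <- layer$mu^2 + omega^2 * layer$eta^2
    film_f <- layer$h * layer$rho * omega -
      2 * layer$h * liq^2 * layer$eta * omega^2 / denom
    film_D <- 2 * layer$h * liq^2 * layer$mu * omega / denom
  }
  liq_f <- if (reference == "unloaded") liq else 0
  liq_D <- if (reference == "unloaded") 2 * liq else 0
  data.frame(
    harmonic = harmonics,
    df_Hz = -(liq_f + film_f) / (2 * pi * mq),
    dD = (liq_D + film_D) / (2 * pi * harmonics * sensor$f1 * mq)
  )
}

#' Fit a Kelvin-Voigt layer to multi-harmonic QCM-D shifts
#'
#' Weighted nonlinear least squares over `(h, eta, mu)` at fixed film
#' density, jointly on frequency and dissipation residuals across
#' harmonics (the paper-style analysis uses the 7th, 9th and 11th).
#' Residuals are weighted by per-channel noise scales; parameters are
#' fitted on the log scale with a deterministic multi-start grid and the
#' best-residual solution retained.
#'
#' @param data Data frame with columns `harmonic`, `df_Hz`, `dD` holding
#'   the liquid-referenced plateau shifts per harmonic, or a full trace
#'   (columns `time_s`, `harmonic`, `df_Hz`, `dD`) together with `window`.
#' @param window Optional length-2 time interval (s) averaged per harmonic
#'   when `data` is a trace.
#' @param rho_film Assumed film density in kg m^-3 (fixed, default 1050).
#' @param fluid A [bulk_fluid()].
#' @param sensor A [quartz_sensor()].
#' @param noise_f,noise_D Residual scales for the frequency (Hz) and
#'   dissipation (absolute) channels, e.g. baseline-window standard
#'   deviations.
#' @return Object of class `"kv_fit"`: the best-fit
#'   [viscoelastic_layer()], acoustic mass `mass` (ng cm^-2), parameter
#'   standard errors, residuals, residual norm and a convergence flag.
#' @seealso [kelvin_voigt_forward()], [sauerbrey_mass()]
#' @export
kv_fit <- function(data, window = NULL, rho_film = 1050,
                   fluid = bulk_fluid(), sensor = quartz_sensor(),
                   noise_f = 1, noise_D = 1e-6) {
  if (!is.null(window) && "time_s" %in% names(data)) {
    sel <- data$time_s >= window[1] & data$time_s <= window[2]
    data <- aggregate(cbind(df_Hz, dD) ~ harmonic, data = data[sel, ], mean)
  }
  stopifnot(all(c("harmonic", "df_Hz", "dD") %in% names(data)))
  .check_harmonic(data$harmonic)
  if (nrow(data) < 2) {
    stop("kv_fit needs shifts for at least 2 harmonics", call. = FALSE)
  }
  if (nrow(data) < 3) {
    warning("fewer than 3 harmonics: fit is poorly constrained")
  }
  stopifnot(rho_film > 0)

  resid_fun <- function(logpar) {
    layer <- viscoelastic_layer(h = exp(logpar[1]), rho = rho_film,
                                eta = exp(logpar[2]), mu = exp(logpar[3]))
    pred <- kelvin_voigt_forward(layer, fluid, sensor, data$harmonic)
    c((pred$df_Hz - data$df_Hz) / noise_f, (pred$dD - data$dD) / noise_D)
  }

  # deterministic multi-start over physically plausible decades
  starts <- expand.grid(h = c(1e-9, 5e-9, 2e-8),
                        eta = c(1e-3, 3e-3),
                        mu = c(1e4, 1e6, 1e8))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- log(as.numeric(starts[i, ]))
    fit <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("Kelvin-Voigt fit failed from all starts",
                          call. = FALSE)
  converged <- best$info %in% 1:4
  p <- best$par
  layer <- viscoelastic_layer(exp(p[1]), rho_film, exp(p[2]), exp(p[3]))

  # parameter covariance on the log scale from the LM Jacobian
  dof <- max(1L, 2L * nrow(data) - 3L)
  s2 <- best$deviance / dof
  vc <- try(solve(best$hessian) * s2, silent = TRUE)
  se_log <- if (inherits(vc, "try-error")) rep(NA_real_, 3) else
    sqrt(pmax(diag(vc), 0))

  structure(list(
    layer = layer, mass = layer_mass(layer), rho_film = rho_film,
    se_log = stats::setNames(se_log, c("log_h", "log_eta", "log_mu")),
    mass_se = layer_mass(layer) * se_log[1],
    data = data, fluid = fluid, sensor = sensor,
    residuals = resid_fun(p), deviance = best$deviance,
    converged = converged, info = best$info, message = best$message
  ), class = "kv_fit")
}

#' @export
print.kv_fit <- function(x, ...) {
  cat("Kelvin-Voigt viscoelastic fit (", nrow(x$data), " harmonics)\n",
      sep = "")
  cat(sprintf("  acoustic mass: %.3g ng cm^-2 (rho*h, rho fixed at %g kg m^-3)\n",
              x$mass, x$rho_film))
  cat(sprintf("  h = %.3g nm, eta = %.3g kg m^-1 s^-1, mu = %.3g Pa\n",
              x$layer$h * 1e9, x$layer$eta, x$layer$mu))
  cat(sprintf("  residual norm: %.3g; converged: %s\n",
              sqrt(x$deviance), x$converged))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence:",
                        x$message, "\n")
  invisible(x)
}

#' @export
coef.kv_fit <- function(object, ...) {
  c(h = object$layer$h, eta = object$layer$eta, mu = object$layer$mu,
    mass = object$mass)
}

#' @export
predict.kv_fit <- function(object, harmonics = object$data$harmonic, ...) {
  kelvin_voigt_forward(object$layer, object$fluid, object$sensor, harmonics)
}

#' @export
residuals.kv_fit <- function(object, ...) object$residuals

#' @export
summary.kv_fit <- function(object, ...) {
  out <- list(fit = object,
              sauerbrey = mean(sauerbrey_mass(object$data$df_Hz,
                                              object$data$harmonic,
                                              object$sensor)))
  class(out) <- "summary.kv_fit"
  out
}

#' @export
print.summary.kv_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  per-harmonic Sauerbrey mass (mean): %.3g ng cm^-2\n",
              x$sauerbrey))
  cat(sprintf("  log-parameter SE: %s\n",
              paste(sprintf("%s=%.2g", names(x$fit$se_log), x$fit$se_log),
                    collapse = ", ")))
  invisible(x)
}

#' Initial attachment rate from a surface-mass time series
#'
#' Ordinary linear fit of surface mass against time over a declared
#' early-time window; the slope is reported per minute.
#'
#' @param time Time in seconds.
#' @param mass Surface mass density in ng cm^-2.
#' @param window Length-2 time interval (s) after injection.
#' @return List with `rate` (ng cm^-2 min^-1), `se` (same units) and the
#'   underlying `lm` fit.
#' @export
initial_attachment_rate <- function(time, mass, window = range(time)) {
  sel <- time >= window[1] & time <= window[2]
  if (sum(sel) < 3) {
    stop("initial_attachment_rate needs >= 3 points in the window",
         call. = FALSE)
  }
  fit <- stats::lm(mass[sel] ~ time[sel])
  sm <- summary(fit)$coefficients
  list(rate = unname(sm[2, 1]) * 60, se = unname(sm[2, 2]) * 60, fit = fit)
}
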