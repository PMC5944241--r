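# Independent oracles, kept deliberately naive and separate from the
# package implementation paths they check.

# Physical constants, re-stated here rather than taken from the package.
ORC <- list(e = 1.602176634e-19, kB = 1.380649e-23,
            eps0 = 8.8541878128e-12, N_A = 6.02214076e23,
            R = 8.314462618)

# Gouy-Chapman potential via the tanh/atanh (gamma) parameterization,
# algebraically distinct from the asinh closed form used in the package.
oracle_gc_potential <- function(sigma, c_elec, temperature, eps_r) {
  kT <- ORC$kB * temperature
  n0 <- 1000 * ORC$N_A * c_elec
  kappa <- sqrt(2 * n0 * ORC$e^2 / (eps_r * ORC$eps0 * kT))
  # solve sigma = eps*eps0*kappa*(2kT/e)*sinh(e*phi/(2kT)) for phi
  a <- sigma * ORC$e / (2 * kT * eps_r * ORC$eps0 * kappa)
  2 * kT / ORC$e * log(a + sqrt(a^2 + 1))
}

# Brute-force periodic minimum distance: enumerate the 27 image shifts
# explicitly instead of the round() minimum-image convention.
oracle_min_dist <- function(p, q, box) {
  shifts <- expand.grid(sx = -1:1, sy = -1:1, sz = -1:1)
  best <- Inf
  for (s in seq_len(nrow(shifts))) {
    d <- sqrt(sum((p - (q + c(shifts$sx[s], shifts$sy[s], shifts$sz[s]) *
                          box))^2))
    if (d < best) best <- d
  }
  best
}

# All-pairs bound-monomer counting oracle (O(N*M*27) loops).
oracle_bound_counts <- function(geom) {
  sc <- geom$sidechains
  P <- geom$phosphorus
  counts <- integer(0)
  for (pep in sort(unique(sc$peptide))) {
    rows <- which(sc$peptide == pep)
    nb <- 0L
    for (i in rows) {
      cutoff <- geom$cutoffs[[sc$type[i]]]
      mind <- Inf
      for (j in seq_len(nrow(P))) {
        d <- oracle_min_dist(c(sc$x[i], sc$y[i], sc$z[i]),
                             c(P$x[j], P$y[j], P$z[j]), geom$box)
        if (d < mind) mind <- d
      }
      if (mind <= cutoff) nb <- nb + 1L
    }
    counts <- c(counts, nb)
  }
  counts
}

# Trapezoid cumulative integral written directly (checks pracma usage).
oracle_cumtrapz <- function(x, y) {
  n <- length(x)
  out <- numeric(n)
  for (i in 2:n) {
    out[i] <- out[i - 1] + 0.5 * (y[i] + y[i - 1]) * (x[i] - x[i - 1])
  }
  out
}

make_trace <- function(df, dD, harmonic, time = seq_along(df)) {
  data.frame(time_s = time, harmonic = harmonic, df_Hz = df, dD = dD)
}
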