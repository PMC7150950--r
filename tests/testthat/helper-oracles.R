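# Shared fixtures and independent oracles used across the suite.

air_default <- air_properties()

# independent numeric oracle for the gravitational deposition efficiency in
# horizontal laminar tube flow: eta = (16/(3 pi)) Int_0^1 min(kappa,
# (1-b^2)^(3/2)) db, derived from chord-flux accounting (flux below the
# critical entry height equals v_s * L per unit width, capped by the chord
# flux)
eta_sedimentation_quadrature <- function(kappa) {
  f <- function(b) pmin(kappa, (1 - b^2)^(3 / 2))
  (16 / (3 * pi)) * integrate(f, 0, 1, rel.tol = 1e-10)$value
}

# slender-body asymptotic resistances of a long fiber (independent of the
# elliptic-integral implementation)
slender_body_resistance <- function(b_p, AR) {
  list(K_par = 4 * pi * b_p / (log(2 * AR) - 0.5),
       K_perp = 8 * pi * b_p / (log(2 * AR) + 0.5))
}

# measure the Jeffery tumbling period of a fiber in simple shear by
# accumulating the in-plane rotation of the orientation vector
measure_jeffery_period <- function(AR, rate = 10, dt = NULL,
                                   air = air_default) {
  spec <- fiber_spec(2e-6, AR, air = air)
  shear <- simple_shear_field(rate)
  if (is.null(dt)) dt <- 0.002 / rate * 10 # ~3e3 steps per period at AR=10
  st <- fiber_state(c(0, 0, 0), orientation = unit(c(1, 1e-3, 0)))
  t_expect <- 2 * pi * (AR + 1 / AR) / rate
  prev <- st$orientation
  rot <- 0
  for (i in seq_len(ceiling(1.5 * t_expect / dt))) {
    st <- advance_state(st, spec, shear, air, dt, gravity = c(0, 0, 0),
                        lift = FALSE)
    p <- st$orientation
    rot <- rot + asin(max(min(prev[1] * p[2] - prev[2] * p[1], 1), -1))
    prev <- p
    if (abs(rot) >= 2 * pi) return(st$time)
  }
  NA_real_
}

# flux-weighted sample of entry positions on the inlet disc of a tube
# (rejection sampling proportional to the parabolic profile)
seed_flux_weighted <- function(n, radius, seed = 1) {
  set.seed(seed)
  pts <- matrix(0, n, 3)
  k <- 0
  while (k < n) {
    y <- runif(1, -radius, radius)
    z <- runif(1, -radius, radius)
    r2 <- y^2 + z^2
    if (r2 < radius^2 && runif(1) < 1 - r2 / radius^2) {
      k <- k + 1
      pts[k, ] <- c(0, y, z)
    }
  }
  pts
}

# monotone non-decreasing allowing a binomial-noise slack (2 pooled SE)
monotone_increasing_with_slack <- function(p, n) {
  ok <- TRUE
  for (i in seq_len(length(p) - 1)) {
    se <- sqrt(pmax(p[i] * (1 - p[i]), 1e-4) / n)
    if (p[i + 1] < p[i] - 2 * se) ok <- FALSE
  }
  ok
}

unit <- function(v) v / sqrt(sum(v^2))
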