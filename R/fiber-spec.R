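# Fiber geometry and aerodynamic descriptors.
#
# A fiber is a prolate spheroid with minor semi-axis a_p and major semi-axis
# b_p = AR * a_p, volume-matched to a sphere of diameter d_p.  Its
# Stokes-regime behaviour is summarized by the Stokes-equivalent diameter
# d_Stk (diameter of the sphere with the same orientation-averaged drag
# relaxation), the relaxation time t0, and the Stokes number Stk.

#' Air properties
#'
#' Physical properties of the carrier gas plus gravitational acceleration.
#' Defaults are dry air at roughly body-ambient conditions.
#'
#' @param mu dynamic viscosity (Pa s).
#' @param rho density (kg/m^3).
#' @param g gravitational acceleration magnitude (m/s^2).
#' @return An object of class `air_properties`.
#' @export
#' @examples
#' air_properties()
air_properties <- function(mu = 1.81e-5, rho = 1.204, g = 9.81) {
  stopifnot(mu > 0, rho > 0, g >= 0)
  structure(list(mu = mu, rho = rho, g = g), class = "air_properties")
}

#' Semi-axes of a volume-equivalent prolate spheroid
#'
#' Solves for the minor (`a_p`) and major (`b_p = AR * a_p`) semi-axes of a
#' prolate spheroid with aspect ratio `AR` whose volume equals that of a
#' sphere of diameter `d_p`: (4/3) pi a_p^2 b_p = (4/3) pi (d_p/2)^3, hence
#' a_p = (d_p/2) AR^(-1/3).
#'
#' @param d_p volume-equivalent sphere diameter (m).
#' @param AR aspect ratio (>= 1; 1 is a sphere).
#' @return Named list with `a_p` and `b_p` in metres.
#' @export
#' @examples
#' fiber_axes(2e-6, 8) # a_p = 0.5 um, b_p = 4 um
fiber_axes <- function(d_p, AR) {
  stopifnot(d_p > 0)
  if (any(AR < 1)) stop("oblate not supported: AR must be >= 1")
  a_p <- (d_p / 2) * AR^(-1 / 3)
  list(a_p = a_p, b_p = AR * a_p)
}

#' Stokes-equivalent diameter of a prolate spheroid
#'
#' Diameter of the sphere with the same Stokes-regime aerodynamic relaxation
#' as the fiber:
#' `d_Stk = 2 a_p sqrt( AR * ln(AR + sqrt(AR^2 - 1)) / sqrt(AR^2 - 1) )`.
#' The AR -> 1 limit of the bracket is 1, so a sphere returns its own
#' diameter; the limit is taken analytically (series in (AR - 1)) near 1 to
#' avoid 0/0 cancellation.
#'
#' @param a_p minor semi-axis (m).
#' @param AR aspect ratio (>= 1).
#' @return `d_Stk` in metres, `<= d_p` with equality iff `AR = 1`.
#' @export
#' @examples
#' stokes_diameter(1e-6, 1) # == 2e-6
stokes_diameter <- function(a_p, AR) {
  stopifnot(a_p > 0, AR >= 1)
  n <- max(length(a_p), length(AR))
  a_p <- rep_len(a_p, n); AR <- rep_len(AR, n)
  fac <- ifelse(AR > 1 + 1e-8, {
    x <- sqrt(pmax(AR^2 - 1, 0))
    AR * log(AR + x) / x
  },
  # ln(AR + sqrt(AR^2-1))/sqrt(AR^2-1) = 1 - e/3·... with e = AR - 1:
  # series of AR*asinh-type bracket about AR = 1: AR*(1 - (AR^2-1)/6 + ...)
  AR * (1 - (AR^2 - 1) / 6 + 3 * (AR^2 - 1)^2 / 40))
  2 * a_p * sqrt(fac)
}

#' Stokes-drag relaxation time
#'
#' `t0 = rho_p d_Stk^2 / (18 mu_air)`: the timescale over which the particle
#' velocity equilibrates with the surrounding flow.
#'
#' @param d_stk Stokes-equivalent diameter (m).
#' @param rho_p particle density (kg/m^3).
#' @param mu_air air dynamic viscosity (Pa s).
#' @return relaxation time (s).
#' @export
relaxation_time <- function(d_stk, rho_p = 1000, mu_air = 1.81e-5) {
  stopifnot(d_stk >= 0, rho_p > 0, mu_air > 0)
  rho_p * d_stk^2 / (18 * mu_air)
}

#' Stokes number
#'
#' `Stk = t0 u0 / D`, with `u0` the maximal inlet velocity of a domain at
#' peak inhalation and `D` the inlet diameter.  Small-Stk particles behave
#' as flow tracers; large-Stk particles impact where streamlines turn.
#'
#' @param t0 relaxation time (s).
#' @param u0 characteristic inlet velocity (m/s).
#' @param D inlet diameter (m).
#' @return dimensionless Stokes number.
#' @export
stokes_number <- function(t0, u0, D) {
  stopifnot(D > 0)
  t0 * u0 / D
}

#' Define one fiber particle group
#'
#' Bundles the geometric and aerodynamic description of a particle group:
#' semi-axes, Stokes-equivalent diameter, relaxation time, mass, and the
#' Oberbeck translational resistance coefficients (see [drag_force()]).
#'
#' @param d_p volume-equivalent sphere diameter (m).
#' @param AR aspect ratio (>= 1).
#' @param rho_p particle density (kg/m^3); default 1000 (unit-density
#'   aerosol standard).
#' @param air [air_properties()] used for derived quantities.
#' @return An object of class `fiber_spec`.
#' @export
#' @examples
#' fiber_spec(2e-6, 10)
fiber_spec <- function(d_p, AR, rho_p = 1000, air = air_properties()) {
  stopifnot(d_p > 0, AR >= 1, rho_p > 0)
  ax <- fiber_axes(d_p, AR)
  d_stk <- stokes_diameter(ax$a_p, AR)
  t0 <- relaxation_time(d_stk, rho_p, air$mu)
  K <- oberbeck_resistance(ax$a_p, AR)
  structure(list(
    d_p = d_p, AR = AR, a_p = ax$a_p, b_p = ax$b_p,
    rho_p = rho_p, d_stk = d_stk, t0 = t0,
    mass = rho_p * (4 / 3) * pi * (d_p / 2)^3,
    K_par = K$K_par, K_perp = K$K_perp,
    lambda = (AR^2 - 1) / (AR^2 + 1)
  ), class = "fiber_spec")
}

#' @export
print.fiber_spec <- function(x, ...) {
  cat(sprintf(
    "<fiber_spec> d_p = %.3g um, AR = %.3g (a_p = %.3g um, b_p = %.3g um)\n",
    x$d_p * 1e6, x$AR, x$a_p * 1e6, x$b_p * 1e6
  ))
  cat(sprintf("  rho_p = %g kg/m^3, d_Stk = %.4g um, t0 = %.4g s\n",
              x$rho_p, x$d_stk * 1e6, x$t0))
  invisible(x)
}
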