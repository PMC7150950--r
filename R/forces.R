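# Forces and torques on a prolate spheroid in Stokes flow.

#' Oberbeck translational resistance coefficients
#'
#' Stokes-flow resistance of a prolate spheroid with semi-axes
#' (`a_p`, `a_p`, `b_p = AR a_p`), from the classical elliptic-integral
#' solution.  The drag on a spheroid moving with slip velocity `u` is
#' `F = mu * K * u` with `K = K_par` for motion along the symmetry axis
#' (lengthwise) and `K = K_perp` broadside.  With eccentricity
#' `e = sqrt(1 - 1/AR^2)` and `L = ln((1+e)/(1-e))`:
#' `K_par  = 16 pi b_p e^3 / ((1 + e^2) L - 2 e)`,
#' `K_perp = 32 pi b_p e^3 / ((3 e^2 - 1) L + 2 e)`.
#' Both reduce to the Stokes value `3 pi d_p` as `AR -> 1`, and their ratio
#' tends (logarithmically) to 2 in the slender limit.
#'
#' @param a_p minor semi-axis (m).
#' @param AR aspect ratio (>= 1).
#' @return list with `K_par`, `K_perp` (m); multiply by `mu * u` for force.
#' @export
oberbeck_resistance <- function(a_p, AR) {
  stopifnot(a_p > 0, AR >= 1)
  b_p <- AR * a_p
  e2 <- 1 - 1 / AR^2
  if (e2 < 1e-6) {
    # series about the sphere (avoids 0/0): K = 6 pi b (1 - c e^2 + O(e^4))
    K0 <- 6 * pi * b_p
    return(list(K_par = K0 * (1 - 2 * e2 / 5), K_perp = K0 * (1 - 3 * e2 / 10)))
  }
  e <- sqrt(e2)
  L <- log((1 + e) / (1 - e))
  list(
    K_par = 16 * pi * b_p * e^3 / ((1 + e2) * L - 2 * e),
    K_perp = 32 * pi * b_p * e^3 / ((3 * e2 - 1) * L + 2 * e)
  )
}

#' Orientation-dependent Stokes drag on a fiber
#'
#' `F = mu [ K_par (p p^T) + K_perp (I - p p^T) ] u_rel`, where `p` is the
#' unit orientation vector along the major axis and `u_rel = u_fluid -
#' v_particle` the slip velocity.  For a sphere this is Stokes' law
#' `3 pi mu d_p u_rel`.
#'
#' @param spec a [fiber_spec()].
#' @param p orientation unit vector (length 3).
#' @param u_rel slip velocity vector (m/s).
#' @param air [air_properties()].
#' @return force vector (N).
#' @export
drag_force <- function(spec, p, u_rel, air = air_properties()) {
  stopifnot(abs(sum(p^2) - 1) < 1e-6)
  upar <- sum(p * u_rel) * p
  uperp <- u_rel - upar
  air$mu * (spec$K_par * upar + spec$K_perp * uperp)
}

#' Quasi-steady Jeffery rotation rate of a spheroid
#'
#' Evolution of the orientation unit vector `p` of an inertialess prolate
#' spheroid in a linear local flow with velocity-gradient tensor `gradu`
#' (`gradu[i, j] = du_i/dx_j`):
#' `dp/dt = W p + lambda (S p - (p' S p) p)`, with `S`/`W` the
#' symmetric/antisymmetric parts of `gradu` and shape factor
#' `lambda = (AR^2 - 1)/(AR^2 + 1)`.  In simple shear of rate `g` the orbit
#' is periodic with the Jeffery period `T = 2 pi (AR + 1/AR)/g`.
#'
#' @param spec a [fiber_spec()].
#' @param p orientation unit vector.
#' @param gradu 3x3 velocity gradient tensor (1/s).
#' @return `dp/dt` (1/s), orthogonal to `p`.
#' @export
jeffery_rotation_rate <- function(spec, p, gradu) {
  S <- (gradu + t(gradu)) / 2
  W <- (gradu - t(gradu)) / 2
  Sp <- as.vector(S %*% p)
  as.vector(W %*% p) + spec$lambda * (Sp - sum(p * Sp) * p)
}

#' Shear-induced (Saffman-type) lift force
#'
#' Lift on a small particle slipping through a sheared flow, evaluated with
#' the Stokes-equivalent diameter as the particle length scale:
#' `F = 1.615 mu d_Stk^2 (u_rel x omega) / sqrt(nu |omega|)`,
#' where `omega = curl(u)` is extracted from `gradu` and `nu` is the air
#' kinematic viscosity.  The force is identically zero in uniform flow
#' (`gradu = 0`) or at zero slip, and pushes a lagging particle toward the
#' faster fluid.  The lift model is pluggable in the trackers (`lift =
#' "saffman"` or `"none"`) so an orientation-resolved form can be
#' substituted.
#'
#' @param spec a [fiber_spec()].
#' @param u_rel slip velocity `u_fluid - v_particle` (m/s).
#' @param gradu 3x3 velocity gradient tensor (1/s).
#' @param air [air_properties()].
#' @return force vector (N).
#' @export
lift_force <- function(spec, u_rel, gradu, air = air_properties()) {
  om <- c(
    gradu[3, 2] - gradu[2, 3],
    gradu[1, 3] - gradu[3, 1],
    gradu[2, 1] - gradu[1, 2]
  )
  nom <- sqrt(sum(om^2))
  if (nom == 0 || all(u_rel == 0)) return(c(0, 0, 0))
  nu <- air$mu / air$rho
  cx <- c(
    u_rel[2] * om[3] - u_rel[3] * om[2],
    u_rel[3] * om[1] - u_rel[1] * om[3],
    u_rel[1] * om[2] - u_rel[2] * om[1]
  )
  1.615 * air$mu * spec$d_stk^2 / sqrt(nu * nom) * cx
}
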