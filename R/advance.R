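# Particle state and time integration.

#' Create a fiber kinematic state
#'
#' @param position,velocity numeric length-3 vectors (m, m/s).
#' @param orientation unit vector along the fiber major axis.
#' @param time clock (s).
#' @param status one of "airborne", "deposited", "exited".
#' @return An object of class `fiber_state`.
#' @export
fiber_state <- function(position, velocity = c(0, 0, 0),
                        orientation = c(1, 0, 0), time = 0,
                        status = "airborne") {
  status <- match.arg(status, c("airborne", "deposited", "exited"))
  structure(list(
    position = as.numeric(position), velocity = as.numeric(velocity),
    orientation = unit(as.numeric(orientation)), time = time,
    status = status
  ), class = "fiber_state")
}

#' Advance a fiber state by one time step
#'
#' One step of the Lagrangian update: the translational equation
#' `m dv/dt = F_drag + F_lift + m g` is integrated with an exponential
#' scheme that is exact for linear drag with coefficients frozen over the
#' step (flow velocity and gradient evaluated at a midpoint predictor
#' position), and the orientation follows quasi-steady Jeffery rotation
#' (RK2, renormalized).  One-way coupling: the flow is not modified.
#'
#' @param state a [fiber_state()], status "airborne".
#' @param spec a [fiber_spec()].
#' @param flow a `flow_field`.
#' @param air [air_properties()].
#' @param dt time step (s, > 0).
#' @param gravity gravity direction override (unit vector); defaults to the
#'   flow domain's (or `-z` for unbounded fields).
#' @param lift include shear lift (default TRUE).
#' @return the updated `fiber_state`.
#' @export
advance_state <- function(state, spec, flow, air = air_properties(), dt,
                          gravity = NULL, lift = TRUE) {
  stopifnot(state$status == "airborne", dt > 0)
  if (is.null(gravity)) {
    gravity <- if (!is.null(flow$domain)) flow$domain$gravity
      else if (!is.null(flow$gravity)) flow$gravity else c(0, 0, -1)
  }
  x <- state$position; v <- state$velocity; p <- state$orientation
  t <- state$time

  xm <- x + 0.5 * dt * v
  u <- as.numeric(field_velocity(flow, xm, t + 0.5 * dt))
  G <- field_gradient(flow, xm, t + 0.5 * dt)

  f <- air$g * gravity
  if (lift) f <- f + lift_force(spec, u - v, G, air) / spec$mass
  apar <- air$mu * spec$K_par / spec$mass
  aper <- air$mu * spec$K_perp / spec$mass
  fpar <- sum(f * p) * p
  fper <- f - fpar
  veq <- u + fpar / apar + fper / aper
  dv <- v - veq
  dvpar <- sum(dv * p) * p
  dvper <- dv - dvpar
  E1 <- exp(-apar * dt); E2 <- exp(-aper * dt)
  v_new <- veq + E1 * dvpar + E2 * dvper
  x_new <- x + dt * veq + (1 - E1) / apar * dvpar + (1 - E2) / aper * dvper

  if (spec$AR > 1) {
    k1 <- jeffery_rotation_rate(spec, p, G)
    pm <- unit(p + 0.5 * dt * k1)
    k2 <- jeffery_rotation_rate(spec, pm, G)
    p <- unit(p + dt * k2)
  }
  if (any(!is.finite(c(x_new, v_new, p)))) {
    stop(sprintf("integration blow-up at t = %g s", t + dt))
  }
  fiber_state(x_new, v_new, p, t + dt)
}

#' Tracking options
#'
#' Numerical policy for the compiled tracker.  In the default desk mode the
#' step is adaptive: `dt = min(dt_max, courant * R / speed)` with an
#' additional `ang_factor / shear` bound resolving fiber rotation; the
#' exponential integrator is exact for linear drag so the particle
#' relaxation time needs no resolution.  Fidelity mode instead uses the
#' fixed discrete-element step `dt = 2e-7` s.
#'
#' @param mode "desk" (adaptive) or "fidelity" (fixed 2e-7 s step).
#' @param dt_max,dt_min adaptive step bounds (s).
#' @param courant displacement per step as a fraction of the local radius.
#' @param ang_factor rotation per step bound (radians-scale).
#' @param lift include shear lift.
#' @param sed_fraction gravity-aligned velocity fraction above which a
#'   non-tip contact is labeled sedimentation (diagnostic convention).
#' @return list of options for [track_fibers()].
#' @export
track_options <- function(mode = c("desk", "fidelity"), dt_max = 1e-3,
                          dt_min = 1e-9, courant = 0.1, ang_factor = 0.05,
                          lift = TRUE, sed_fraction = 0.5) {
  mode <- match.arg(mode)
  list(
    dt_max = dt_max, dt_min = dt_min, courant = courant,
    ang_factor = ang_factor, lift = lift, sed_fraction = sed_fraction,
    fixed_dt = if (mode == "fidelity") 2e-7 else -1
  )
}

#' Track a group of fibers through a flow domain
#'
#' Integrates every particle from its injection time until deposition
#' (wall contact, including fiber-tip interception), exit through a
#' terminal outlet plane, or `t_end`.  Deterministic: no random numbers are
#' drawn.
#'
#' @param field a `flow_field` built on an `airway_domain`.
#' @param spec a [fiber_spec()].
#' @param x n x 3 matrix of initial positions (m).
#' @param v n x 3 matrix of initial velocities (m/s); default local flow.
#' @param p n x 3 matrix of initial orientations; default streamwise.
#' @param t_inject injection times (s), scalar or length n.
#' @param t_end end of the simulation window (s).
#' @param air [air_properties()].
#' @param options [track_options()].
#' @return data.frame of terminal records: status, event time, position,
#'   velocity, orientation, segment, region, outlet, mechanism,
#'   center-to-wall distance at contact.
#' @export
track_fibers <- function(field, spec, x, v = NULL, p = NULL, t_inject = 0,
                         t_end, air = air_properties(),
                         options = track_options()) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 3)
  n <- nrow(x)
  t_inject <- rep_len(t_inject, n)
  if (is.null(v)) {
    v <- t(vapply(seq_len(n), function(i) {
      as.numeric(field_velocity(field, x[i, ], t_inject[i]))
    }, numeric(3)))
  }
  if (is.null(p)) {
    root <- which(is.na(field$domain$segments$parent))[1]
    sg <- field$domain$segments[root, ]
    p <- matrix(rep(c(sg$dx, sg$dy, sg$dz), each = n), n, 3)
  }
  pack <- pack_field(field)
  sg <- field$domain$segments
  # initial segment: containing segment of each start point
  seg0 <- integer(n)
  best <- rep(-Inf, n)
  for (j in seq_len(nrow(sg))) {
    d <- segment_inside_distance(sg[j, ], x)
    take <- d > best
    best[take] <- d[take]
    seg0[take] <- j
  }
  res <- cpp_track(pack, pack_fiber(spec),
                   air[c("mu", "rho", "g")], x, v, p,
                   as.numeric(t_inject), as.integer(seg0), c(
                     options[c("dt_max", "dt_min", "courant", "ang_factor",
                               "lift", "sed_fraction", "fixed_dt")],
                     list(t_end = t_end)
                   ))
  out <- as.data.frame(res[, 1:16, drop = FALSE])
  out$status <- c("airborne", "deposited", "exited")[out$status]
  out$mechanism <- c("none", "interception", "sedimentation",
                     "impaction")[out$mechanism + 1]
  out$region <- sg$region[out$segment]
  out$outlet <- sg$outlet[out$segment]
  out$outlet[out$status != "exited"] <- NA
  out
}
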