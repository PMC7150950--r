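# DPI inhalation waveform and analytic laminar flow fields.

#' DPI inhalation waveform
#'
#' Piecewise-smooth inspiratory flow-rate profile characteristic of a
#' dry-powder-inhaler maneuver: a sin^2 ramp from zero to the peak flow
#' over `rise_time`, a plateau at `peak_flow`, and a cos^2 decay back to
#' zero at `duration`.  The plateau end `t_h` is solved in closed form so
#' that the time integral of the flow rate equals `tidal_volume`:
#' `t_h = 2 TV / PIFR - T + t_r`.
#'
#' Defaults describe an adult DPI maneuver: tidal volume 2.95 L, peak
#' inspiratory flow 90 L/min, inspiration 3 s, with particle injection
#' confined to a bolus spanning 0.45--0.6 s.
#'
#' @param tidal_volume inhaled volume (L).
#' @param peak_flow peak inspiratory flow rate (L/min).
#' @param duration total inspiration period (s).
#' @param rise_time ramp duration (s); DPI onsets are sharp.
#' @param bolus particle-injection window (s, length 2).
#' @return An object of class `dpi_waveform`.
#' @export
#' @examples
#' wf <- make_dpi_waveform()
#' integrate(function(t) waveform_flow(wf, t) / 60, 0, 3)$value # 2.95 L
make_dpi_waveform <- function(tidal_volume = 2.95, peak_flow = 90,
                              duration = 3, rise_time = 0.4,
                              bolus = c(0.45, 0.6)) {
  stopifnot(tidal_volume > 0, peak_flow > 0, duration > 0,
            rise_time > 0, rise_time < duration,
            length(bolus) == 2, bolus[1] >= 0, bolus[2] > bolus[1],
            bolus[2] <= duration)
  P <- peak_flow / 60 # L/s
  if (P * duration < tidal_volume) {
    stop("infeasible waveform: peak_flow * duration < tidal_volume")
  }
  t_h <- 2 * tidal_volume / P - duration + rise_time
  if (t_h < rise_time || t_h > duration) {
    stop("infeasible waveform: no plateau end satisfies the volume constraint")
  }
  structure(list(
    type = "dpi", tidal_volume = tidal_volume, peak_flow = peak_flow,
    duration = duration, rise_time = rise_time, t_h = t_h, bolus = bolus
  ), class = "dpi_waveform")
}

#' Steady (constant-flow) waveform
#'
#' Constant flow rate, for steady validation cases.
#'
#' @param flow flow rate (L/min).
#' @param duration nominal duration (s).
#' @return An object of class `dpi_waveform` with `type = "constant"`.
#' @export
steady_flow <- function(flow, duration = Inf) {
  stopifnot(flow >= 0)
  structure(list(type = "constant", peak_flow = flow, duration = duration,
                 bolus = c(0, 0)),
            class = "dpi_waveform")
}

#' Evaluate a waveform
#'
#' @param waveform a `dpi_waveform`.
#' @param t times (s).
#' @return flow rate (L/min) at `t`; zero outside `[0, duration]`.
#' @export
waveform_flow <- function(waveform, t) {
  if (waveform$type == "constant") {
    return(rep(waveform$peak_flow, length(t)) * (t >= 0 & t <= waveform$duration))
  }
  P <- waveform$peak_flow
  tr <- waveform$rise_time
  th <- waveform$t_h
  Td <- waveform$duration
  q <- numeric(length(t))
  i1 <- t >= 0 & t < tr
  q[i1] <- P * sin(pi * t[i1] / (2 * tr))^2
  i2 <- t >= tr & t <= th
  q[i2] <- P
  i3 <- t > th & t <= Td
  q[i3] <- P * cos(pi / 2 * (t[i3] - th) / (Td - th))^2
  q
}

#' @export
print.dpi_waveform <- function(x, ...) {
  if (x$type == "constant") {
    cat(sprintf("<dpi_waveform> steady, %.3g L/min\n", x$peak_flow))
  } else {
    cat(sprintf(
      "<dpi_waveform> TV = %.3g L, PIFR = %.3g L/min, T = %.3g s (ramp %.3g s, plateau ends %.4g s)\n",
      x$tidal_volume, x$peak_flow, x$duration, x$rise_time, x$t_h
    ))
    cat(sprintf("  injection bolus %.3g - %.3g s\n", x$bolus[1], x$bolus[2]))
  }
  invisible(x)
}

#' @export
plot.dpi_waveform <- function(x, n = 400, ...) {
  t <- seq(0, if (is.finite(x$duration)) x$duration else 1, length.out = n)
  plot(t, waveform_flow(x, t), type = "l", xlab = "time (s)",
       ylab = "flow rate (L/min)", ...)
  if (x$type == "dpi") {
    b <- x$bolus
    lines(b, waveform_flow(x, b), col = "red", lwd = 3)
    mtext("red: particle injection bolus", side = 3, cex = 0.8)
  }
  invisible(x)
}

#' Lobar ventilation split
#'
#' Fractions of the inhaled flow delivered to each lung lobe, in percent:
#' left upper (LU), left lower (LL), right upper (RU), right middle (RM),
#' right lower (RL).  Defaults are physiologically representative resting
#' estimates (15/31/14/7/33).
#'
#' @param LU,LL,RU,RM,RL percentages; must sum to 100.
#' @return named numeric vector of class `lobar_split`.
#' @export
lobar_split <- function(LU = 15, LL = 31, RU = 14, RM = 7, RL = 33) {
  fr <- c(LU = LU, LL = LL, RU = RU, RM = RM, RL = RL)
  if (any(fr <= 0)) stop("lobar fractions must be positive")
  if (abs(sum(fr) - 100) > 1e-9) stop("lobar fractions must sum to 100%")
  structure(fr, class = "lobar_split")
}

# per-segment flux fractions: leaves get the configured share, interior
# segments the sum of their descendant leaves
segment_fractions <- function(domain, split = NULL) {
  sg <- domain$segments
  n <- nrow(sg)
  frac <- numeric(n)
  leaves <- which(!is.na(sg$outlet))
  if (is.null(split)) {
    frac[leaves] <- 1 / length(leaves)
  } else {
    if (!all(sg$outlet[leaves] %in% names(split))) {
      stop("split labels do not cover the domain outlets")
    }
    frac[leaves] <- unclass(split)[sg$outlet[leaves]] / 100
  }
  for (i in rev(seq_len(n))) { # children always listed after parents
    p <- sg$parent[i]
    if (!is.na(p)) frac[p] <- frac[p] + frac[i]
  }
  if (any(frac < 0)) stop("negative segment flow")
  frac
}

#' Analytic laminar (Poiseuille) flow field on a domain
#'
#' Equips a domain with a time-scaled laminar velocity field: each segment
#' carries its flux share of the waveform flow `Q(t)` with a parabolic
#' axial profile `u(r) = 2 u_bar (1 - (r/R)^2)` (no-slip at the wall), and
#' tapered entrance cones add the continuity-derived radial component so
#' that flux is conserved through constrictions and bifurcations.  The
#' velocity gradient is analytic.  Flux shares at terminal outlets are
#' either equal (`split = NULL`) or a [lobar_split()] matched to outlet
#' labels; interior segments carry the sum of their descendants, so flux is
#' conserved at every bifurcation by construction.
#'
#' @param domain an `airway_domain`.
#' @param waveform a `dpi_waveform` (or a number, taken as steady L/min).
#' @param split `NULL` for equal outlet split, or a [lobar_split()].
#' @param flow_scale dimensionless factor applied to `Q(t)` (used for the
#'   inter-domain hand-off, see [tree_inlet_scale()]).
#' @return An object of class `flow_field`.
#' @export
poiseuille_field <- function(domain, waveform, split = NULL, flow_scale = 1) {
  if (is.numeric(waveform)) waveform <- steady_flow(waveform)
  frac <- segment_fractions(domain, split)
  structure(list(
    domain = domain, waveform = waveform, split = split,
    flow_scale = flow_scale, frac = frac
  ), class = "flow_field")
}

#' Unbounded simple-shear validation field
#'
#' `u = (rate * y, 0, 0)` with constant gradient; used to validate Jeffery
#' rotation and lift against closed forms.
#'
#' @param rate shear rate (1/s).
#' @param gravity gravity unit vector (for trackers; default `-z`).
#' @return An object of class `flow_field`.
#' @export
simple_shear_field <- function(rate, gravity = c(0, 0, -1)) {
  structure(list(domain = NULL, rate = rate, gravity = gravity,
                 waveform = steady_flow(0), flow_scale = 1),
            class = c("shear_field", "flow_field"))
}

#' Evaluate the fluid velocity of a flow field
#'
#' @param field a `flow_field`.
#' @param x position vector (length 3) or n x 3 matrix (m).
#' @param t time (s, scalar).
#' @return n x 3 matrix of velocities (m/s); zero for points outside the
#'   lumen.
#' @export
field_velocity <- function(field, x, t = 0) {
  pts <- if (is.matrix(x)) x else matrix(x, ncol = 3)
  if (inherits(field, "shear_field")) {
    return(cbind(field$rate * pts[, 2], 0, 0))
  }
  cpp_field_velocity(pack_field(field), pts, t)
}

#' Evaluate the velocity-gradient tensor of a flow field
#'
#' @inheritParams field_velocity
#' @param x position vector (length 3).
#' @return 3x3 matrix `G[i, j] = du_i/dx_j` (1/s).
#' @export
field_gradient <- function(field, x, t = 0) {
  if (inherits(field, "shear_field")) {
    G <- matrix(0, 3, 3)
    G[1, 2] <- field$rate
    return(G)
  }
  matrix(cpp_field_gradient(pack_field(field), as.numeric(x), t), 3, 3)
}

# mean inlet velocity of a field, time-averaged over the waveform
mean_inlet_velocity <- function(field) {
  root <- which(is.na(field$domain$segments$parent))[1]
  R <- field$domain$segments$radius0[root]
  wf <- field$waveform
  Td <- if (is.finite(wf$duration)) wf$duration else 1
  qbar <- integrate(function(t) waveform_flow(wf, t), 0, Td,
                    rel.tol = 1e-9)$value / Td # L/min
  qbar / 60000 * field$flow_scale * field$frac[root] / (pi * R^2)
}

#' Inter-domain hand-off scaling and delay
#'
#' When the bronchial tree is simulated as a separate domain fed by the
#' upper airways, particles crossing over have their velocities scaled by
#' the ratio of the time-averaged mean inlet velocities of the two domains,
#' and their arrival is delayed by the time it takes the mean flow to fill
#' the upstream domain volume.
#'
#' @param upstream,downstream `flow_field`s.
#' @return list with `scale` (dimensionless) and `delay` (s).
#' @export
handoff_scale <- function(upstream, downstream) {
  u_up <- mean_inlet_velocity(upstream)
  if (u_up <= 0) stop("no flow in upstream domain")
  u_dn <- mean_inlet_velocity(downstream)
  wf <- upstream$waveform
  Td <- if (is.finite(wf$duration)) wf$duration else 1
  qbar <- integrate(function(t) waveform_flow(wf, t), 0, Td,
                    rel.tol = 1e-9)$value / Td / 60000 *
    upstream$flow_scale # m^3/s
  list(scale = u_dn / u_up, delay = domain_volume(upstream$domain) / qbar)
}

#' Flow-rate scale for the bronchial-tree inlet
#'
#' The DPI flow profile imposed at the tree inlet is scaled so that the
#' mean tree-inlet velocity equals the mean velocity leaving the upstream
#' outlets (velocity continuity across the multiscale hand-off):
#' `scale = A_tree_inlet / sum(A_upstream_outlets)`.
#'
#' @param upper_domain,tree_domain `airway_domain`s.
#' @return dimensionless flow scale to pass to [poiseuille_field()].
#' @export
tree_inlet_scale <- function(upper_domain, tree_domain) {
  sg_u <- upper_domain$segments
  out <- which(!is.na(sg_u$outlet))
  root <- which(is.na(tree_domain$segments$parent))[1]
  tree_domain$segments$radius0[root]^2 / sum(sg_u$radius[out]^2)
}

#' Reynolds-number profile along the airway path
#'
#' Diagnostic Reynolds numbers `Re = rho u_bar D / mu` at peak flow, at the
#' upper-surrogate inlet and at each bronchial-tree level, based on the
#' per-branch mean velocity.
#'
#' @param upper_field,tree_field `flow_field`s.
#' @param air [air_properties()].
#' @return data.frame with station labels, diameters, mean velocities, Re.
#' @export
reynolds_profile <- function(upper_field, tree_field,
                             air = air_properties()) {
  peak_q <- function(field) {
    wf <- field$waveform
    max(waveform_flow(wf, seq(0, if (is.finite(wf$duration)) wf$duration else 1,
                              length.out = 500))) / 60000 * field$flow_scale
  }
  rows <- list()
  sg <- upper_field$domain$segments
  root <- which(is.na(sg$parent))[1]
  D <- 2 * sg$radius[root]
  u <- peak_q(upper_field) * upper_field$frac[root] / (pi * sg$radius[root]^2)
  rows[[1]] <- data.frame(station = "upper inlet", D = D, u_mean = u,
                          Re = air$rho * u * D / air$mu)
  sg <- tree_field$domain$segments
  qt <- peak_q(tree_field)
  for (g in sort(unique(sg$generation))) {
    j <- which(sg$generation == g)[1]
    D <- 2 * sg$radius[j]
    u <- qt * tree_field$frac[j] / (pi * sg$radius[j]^2)
    rows[[length(rows) + 1]] <- data.frame(
      station = paste0("tree g", g), D = D, u_mean = u,
      Re = air$rho * u * D / air$mu
    )
  }
  do.call(rbind, rows)
}
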