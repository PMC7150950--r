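# Parameter-sweep orchestration: bolus injection, two-domain hand-off,
# deposition efficiency and dispersion statistics.

#' Sweep configuration
#'
#' Defines the particle-group grid and the simulation conditions.  The
#' default grid is the 36-group study design: equivalent diameters
#' 1--7, 10 and 20 um crossed with aspect ratios 1, 3, 10 and 30, at 3000
#' particles per group (108,000 total).  For desk-scale runs reduce
#' `n_per_group` (e.g. 500).
#'
#' @param d_p equivalent diameters (m).
#' @param AR aspect ratios.
#' @param n_per_group particles per (d_p, AR) group.
#' @param seed integer random seed (governs only the subsampling of seed
#'   points when `n_per_group` is smaller than the seed grid; the physics
#'   is deterministic).
#' @param rho_p particle density (kg/m^3).
#' @param waveform a [make_dpi_waveform()].
#' @param upper,tree the two airway domains.
#' @param split a [lobar_split()] for the upper-domain outlets.
#' @param air [air_properties()].
#' @param options [track_options()].
#' @param dispersion_radius named list with neighborhood radii (m) for the
#'   dispersion index per domain.
#' @param seed_grid_points size of the inlet seed lattice; groups smaller
#'   than the lattice are a seeded subsample of its points (the only
#'   stochastic element), larger groups revisit points round-robin.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(d_p = c(1:7, 10, 20) * 1e-6,
                         AR = c(1, 3, 10, 30),
                         n_per_group = 3000,
                         seed = 1,
                         rho_p = 1000,
                         waveform = make_dpi_waveform(),
                         upper = build_upper_surrogate(),
                         tree = build_bronchial_tree(),
                         split = lobar_split(),
                         air = air_properties(),
                         options = track_options(),
                         dispersion_radius = list(upper = 10e-3,
                                                  tree = 5e-3),
                         seed_grid_points = 3000) {
  stopifnot(all(d_p > 0), all(AR >= 1), n_per_group >= 0,
            seed_grid_points >= 1)
  structure(list(
    d_p = d_p, AR = AR, n_per_group = n_per_group, seed = as.integer(seed),
    rho_p = rho_p, waveform = waveform, upper = upper, tree = tree,
    split = split, air = air, options = options,
    dispersion_radius = dispersion_radius,
    seed_grid_points = seed_grid_points
  ), class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat(sprintf(
    "<sweep_config> %d groups (%d d_p x %d AR), %d particles/group (%d total), seed %d\n",
    length(x$d_p) * length(x$AR), length(x$d_p), length(x$AR),
    x$n_per_group, length(x$d_p) * length(x$AR) * x$n_per_group, x$seed
  ))
  invisible(x)
}

# map a particle exiting an upstream outlet onto the downstream inlet disc,
# preserving the relative radial position and azimuth, rotating velocity
# and orientation from the outlet frame to the inlet frame
map_to_inlet <- function(exit_seg, tree_root, pos, vel, ori, scale) {
  d_out <- c(exit_seg$dx, exit_seg$dy, exit_seg$dz)
  e1o <- perp_vector(d_out); e2o <- cross3(d_out, e1o)
  tip <- c(exit_seg$x0, exit_seg$y0, exit_seg$z0) + exit_seg$length * d_out
  rel <- pos - tip
  a <- sum(rel * e1o); b <- sum(rel * e2o)
  r <- sqrt(a^2 + b^2)
  rfrac <- min(r / exit_seg$radius, 0.999)
  phi <- atan2(b, a)
  d_in <- c(tree_root$dx, tree_root$dy, tree_root$dz)
  e1i <- perp_vector(d_in); e2i <- cross3(d_in, e1i)
  o_in <- c(tree_root$x0, tree_root$y0, tree_root$z0)
  pos_new <- o_in + rfrac * tree_root$radius0 *
    (cos(phi) * e1i + sin(phi) * e2i)
  tov <- function(w) { # rotate a vector between the two frames
    comp <- c(sum(w * d_out), sum(w * e1o), sum(w * e2o))
    comp[1] * d_in + comp[2] * e1i + comp[3] * e2i
  }
  list(position = pos_new, velocity = scale * tov(vel),
       orientation = unit(tov(ori)))
}

#' Run the full deposition sweep
#'
#' For every (d_p, AR) group: particles are released from the upper-domain
#' inlet seed grid at uniformly spaced times across the injection bolus
#' (round-robin over seed points), with initial velocity equal to the local
#' flow and initial orientation streamwise.  Particles escaping the upper
#' surrogate re-enter the bronchial tree inlet after the hand-off delay,
#' with velocities scaled by the hand-off factor and orientation retained
#' (rotated into the tree inlet frame); the run ends with the inspiration.
#' Fully reproducible from the seed.
#'
#' @param config a [sweep_config()].
#' @param progress print per-group progress lines.
#' @return An object of class `fiber_sweep`: per-group results (`results`),
#'   per-particle terminal records (`records`), a conservation ledger, the
#'   hand-off parameters and the configuration.
#' @export
run_sweep <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  wf <- config$waveform
  up_field <- poiseuille_field(config$upper, wf, config$split)
  tr_field <- poiseuille_field(config$tree, wf,
                               flow_scale = tree_inlet_scale(config$upper,
                                                             config$tree))
  ho <- handoff_scale(up_field, tr_field)
  t_end <- wf$duration
  sg_up <- config$upper$segments
  tree_root <- config$tree$segments[
    which(is.na(config$tree$segments$parent))[1], ]

  groups <- expand.grid(d_p = config$d_p, AR = config$AR,
                        KEEP.OUT.ATTRS = FALSE)
  groups <- groups[order(groups$AR, groups$d_p), ]
  rownames(groups) <- NULL
  n <- config$n_per_group

  grid <- if (n > 0) {
    inlet_seed_grid(config$upper, config$seed_grid_points)
  }
  results <- list()
  rec_all <- list()
  ledger <- new_ledger(sprintf("d%g_AR%g", groups$d_p * 1e6, groups$AR))

  for (gi in seq_len(nrow(groups))) {
    d_p <- groups$d_p[gi]; AR <- groups$AR[gi]
    gid <- sprintf("d%g_AR%g", d_p * 1e6, AR)
    if (n == 0) {
      results[[gi]] <- data.frame(
        group = gid, d_p_um = d_p * 1e6, AR = AR, n_injected = 0L,
        n_deposited_upper = 0L, n_entered_tree = 0L, n_deposited_tree = 0L,
        n_exited = 0L, n_airborne = 0L, de_upper = NA_real_,
        de_tree = NA_real_, disp_upper = NA_real_, disp_tree = NA_real_
      )
      next
    }
    spec <- fiber_spec(d_p, AR, config$rho_p, config$air)
    m <- nrow(grid$points)
    idx <- if (m > n) {
      set.seed(config$seed + 1009L * gi)
      sort(sample.int(m, n))
    } else {
      rep_len(seq_len(m), n)
    }
    x0 <- grid$points[idx, , drop = FALSE]
    t0 <- seq(wf$bolus[1], wf$bolus[2], length.out = n)
    ledger <- ledger_update(ledger, "inject", gid, n)

    rec_up <- track_fibers(up_field, spec, x0, t_inject = t0, t_end = t_end,
                           air = config$air, options = config$options)
    rec_up$particle_id <- seq_len(n)
    rec_up$domain <- "upper"

    ex <- which(rec_up$status == "exited")
    n_dep_up <- sum(rec_up$status == "deposited")
    ledger <- ledger_update(ledger, "deposit", gid, n_dep_up, where = "upper")

    # hand-off into the tree
    rec_tr <- NULL
    n_entered <- 0L
    n_transit <- 0L
    if (length(ex) > 0) {
      t_new <- rec_up$t[ex] + ho$delay
      live <- t_new < t_end
      n_transit <- sum(!live)
      exl <- ex[live]
      n_entered <- length(exl)
      if (n_entered > 0) {
        xs <- vs <- ps <- matrix(0, n_entered, 3)
        for (k in seq_along(exl)) {
          i <- exl[k]
          mp <- map_to_inlet(sg_up[rec_up$segment[i], ], tree_root,
                             c(rec_up$x[i], rec_up$y[i], rec_up$z[i]),
                             c(rec_up$vx[i], rec_up$vy[i], rec_up$vz[i]),
                             c(rec_up$px[i], rec_up$py[i], rec_up$pz[i]),
                             ho$scale)
          xs[k, ] <- mp$position; vs[k, ] <- mp$velocity
          ps[k, ] <- mp$orientation
        }
        rec_tr <- track_fibers(tr_field, spec, xs, v = vs, p = ps,
                               t_inject = t_new[live], t_end = t_end,
                               air = config$air, options = config$options)
        rec_tr$particle_id <- rec_up$particle_id[exl]
        rec_tr$domain <- "tree"
      }
    }
    n_dep_tr <- if (is.null(rec_tr)) 0L else sum(rec_tr$status == "deposited")
    n_out <- if (is.null(rec_tr)) 0L else sum(rec_tr$status == "exited")
    if (n_dep_tr > 0) ledger <- ledger_update(ledger, "deposit", gid,
                                              n_dep_tr, where = "tree")
    if (n_out > 0) ledger <- ledger_update(ledger, "exit", gid, n_out,
                                           where = "tree outflow")
    n_air <- n - n_dep_up - n_dep_tr - n_out

    disp_u <- disp_t <- NA_real_
    if (n_dep_up > 0) {
      dep <- rec_up[rec_up$status == "deposited", c("x", "y", "z")]
      disp_u <- mean(dispersion_index(as.matrix(dep),
                                      config$dispersion_radius$upper))
    }
    if (n_dep_tr > 0) {
      dep <- rec_tr[rec_tr$status == "deposited", c("x", "y", "z")]
      disp_t <- mean(dispersion_index(as.matrix(dep),
                                      config$dispersion_radius$tree))
    }
    de_up <- deposition_efficiency(n_dep_up, n)
    de_tr <- if (n_entered > 0) {
      deposition_efficiency(n_dep_tr, n_entered)
    } else {
      NaN
    }
    results[[gi]] <- data.frame(
      group = gid, d_p_um = d_p * 1e6, AR = AR, n_injected = n,
      n_deposited_upper = n_dep_up, n_entered_tree = n_entered,
      n_deposited_tree = n_dep_tr, n_exited = n_out,
      n_airborne = n_air, de_upper = de_up, de_tree = de_tr,
      disp_upper = disp_u, disp_tree = disp_t
    )
    keep <- c("particle_id", "domain", "status", "t", "x", "y", "z",
              "region", "outlet", "mechanism", "wall_dist", "t_inject")
    rec <- rbind(rec_up[, keep], if (!is.null(rec_tr)) rec_tr[, keep])
    rec <- cbind(group = gid, d_p_um = d_p * 1e6, AR = AR, rec)
    rec_all[[gi]] <- rec
    if (progress) {
      message(sprintf(
        "group %-12s DE_upper = %5.3f  DE_tree = %s  (entered %d)",
        gid, de_up, ifelse(is.nan(de_tr), "  NaN", sprintf("%5.3f", de_tr)),
        n_entered
      ))
    }
  }
  ledger_check(ledger)
  if (length(results) == 0) {
    results <- list(data.frame(
      group = character(0), d_p_um = numeric(0), AR = numeric(0),
      n_injected = integer(0), n_deposited_upper = integer(0),
      n_entered_tree = integer(0), n_deposited_tree = integer(0),
      n_exited = integer(0), n_airborne = integer(0),
      de_upper = numeric(0), de_tree = numeric(0),
      disp_upper = numeric(0), disp_tree = numeric(0)
    ))
  }
  structure(list(
    results = do.call(rbind, results),
    records = if (length(rec_all)) do.call(rbind, rec_all) else NULL,
    ledger = ledger,
    handoff = ho,
    config = config
  ), class = "fiber_sweep")
}

#' @export
print.fiber_sweep <- function(x, ...) {
  r <- x$results
  cat(sprintf("<fiber_sweep> %d groups, %d particles\n",
              nrow(r), sum(r$n_injected)))
  cat(sprintf("  hand-off: velocity scale %.3g, delay %.3g s\n",
              x$handoff$scale, x$handoff$delay))
  cat(sprintf("  deposited upper %d, deposited tree %d, exited %d, airborne %d\n",
              sum(r$n_deposited_upper), sum(r$n_deposited_tree),
              sum(r$n_exited), sum(r$n_airborne)))
  invisible(x)
}

#' @export
summary.fiber_sweep <- function(object, ...) {
  r <- object$results
  cat("Deposition efficiency by group:\n")
  print(r[, c("d_p_um", "AR", "de_upper", "de_tree", "n_entered_tree")],
        row.names = FALSE, digits = 3)
  invisible(r)
}

#' @export
as.data.frame.fiber_sweep <- function(x, ...) x$results

#' Plot deposition efficiencies of a sweep
#'
#' Two panels: upper-surrogate and bronchial-tree deposition efficiency as
#' functions of the equivalent diameter, one curve per aspect ratio.
#'
#' @param x a `fiber_sweep`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fiber_sweep <- function(x, ...) {
  r <- x$results
  ars <- sort(unique(r$AR))
  cols <- hcl.colors(length(ars), "Dark 3")
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (panel in c("de_upper", "de_tree")) {
    plot(NA, xlim = range(r$d_p_um), ylim = c(0, 1), log = "x",
         xlab = expression(d[p] ~ (mu * m)), ylab = "deposition efficiency",
         main = if (panel == "de_upper") "upper surrogate" else "bronchial tree",
         ...)
    for (k in seq_along(ars)) {
      rr <- r[r$AR == ars[k], ]
      rr <- rr[order(rr$d_p_um), ]
      lines(rr$d_p_um, rr[[panel]], type = "b", col = cols[k], pch = 16)
    }
    legend("topleft", legend = paste("AR =", ars), col = cols, lty = 1,
           pch = 16, bty = "n", cex = 0.8)
  }
  invisible(x)
}
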