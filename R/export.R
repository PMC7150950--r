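# Result export: CSV tables, legacy-ASCII VTK point clouds and
# centerlines, run manifest, YAML configuration.

#' Write the deposition-efficiency table
#'
#' One row per group and domain with the deposition efficiency and the
#' underlying counts.
#'
#' @param sweep a `fiber_sweep`.
#' @param path output CSV path.
#' @return the table, invisibly.
#' @export
write_de_table <- function(sweep, path) {
  r <- sweep$results
  if (nrow(r) == 0) {
    out <- data.frame(d_p_um = numeric(0), AR = numeric(0),
                      region = character(0), DE = numeric(0),
                      n_entered = integer(0), n_deposited = integer(0))
    write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  up <- data.frame(d_p_um = r$d_p_um, AR = r$AR, region = "upper",
                   DE = r$de_upper, n_entered = r$n_injected,
                   n_deposited = r$n_deposited_upper)
  tr <- data.frame(d_p_um = r$d_p_um, AR = r$AR, region = "tree",
                   DE = r$de_tree, n_entered = r$n_entered_tree,
                   n_deposited = r$n_deposited_tree)
  out <- rbind(up, tr)
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Write per-particle deposition records
#'
#' @param sweep a `fiber_sweep`.
#' @param path output CSV path.
#' @return the records, invisibly.
#' @export
write_deposition_records <- function(sweep, path) {
  rec <- sweep$records
  dep <- rec[rec$status == "deposited",
             c("particle_id", "group", "d_p_um", "AR", "domain", "t",
               "x", "y", "z", "region", "mechanism", "wall_dist")]
  names(dep)[names(dep) == "wall_dist"] <- "center_wall_dist_m"
  write.csv(dep, path, row.names = FALSE)
  invisible(dep)
}

# legacy ASCII VTK PolyData point cloud with optional point scalars
write_vtk_points <- function(points, path, scalars = NULL,
                             scalar_name = "value",
                             title = "fiberdep points") {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  n <- nrow(pts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", n)), con)
  writeLines(apply(format(pts, digits = 9, scientific = TRUE,
                          trim = TRUE), 1, paste, collapse = " "), con)
  writeLines(sprintf("VERTICES %d %d", n, 2 * n), con)
  writeLines(paste(1, seq_len(n) - 1), con)
  if (!is.null(scalars)) {
    writeLines(c(sprintf("POINT_DATA %d", n),
                 sprintf("SCALARS %s float 1", scalar_name),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(scalars, digits = 7, trim = TRUE), con)
  }
  invisible(path)
}

#' Write a deposition map as a VTK point cloud
#'
#' Deposited-particle positions with the dispersion index (neighbor count
#' within `radius`) as point scalar, viewable in ParaView.
#'
#' @param sweep a `fiber_sweep`.
#' @param path output `.vtk` path.
#' @param domain "upper" or "tree".
#' @param radius neighborhood radius (m); defaults to the configured value
#'   for the domain.
#' @return the path, invisibly.
#' @export
write_deposition_vtk <- function(sweep, path, domain = c("upper", "tree"),
                                 radius = NULL) {
  domain <- match.arg(domain)
  if (is.null(radius)) radius <- sweep$config$dispersion_radius[[domain]]
  rec <- sweep$records
  dep <- rec[rec$status == "deposited" & rec$domain == domain, ]
  pts <- as.matrix(dep[, c("x", "y", "z")])
  nn <- dispersion_index(pts, radius)
  write_vtk_points(pts, path, scalars = nn, scalar_name = "neighbor_count",
                   title = sprintf("deposition map (%s)", domain))
  invisible(path)
}

#' Write domain centerlines as VTK polylines
#'
#' Segment centerlines with the local radius as point data, for quick
#' geometry inspection.
#'
#' @param domain an `airway_domain`.
#' @param path output `.vtk` path.
#' @return the path, invisibly.
#' @export
write_centerline_vtk <- function(domain, path) {
  sg <- domain$segments
  n <- nrow(sg)
  p0 <- as.matrix(sg[, c("x0", "y0", "z0")])
  d <- as.matrix(sg[, c("dx", "dy", "dz")])
  p1 <- p0 + d * sg$length
  pts <- rbind(p0, p1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "airway centerlines", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", 2 * n)), con)
  writeLines(apply(format(pts, digits = 9, scientific = TRUE, trim = TRUE),
                   1, paste, collapse = " "), con)
  writeLines(sprintf("LINES %d %d", n, 3 * n), con)
  writeLines(paste(2, seq_len(n) - 1, seq_len(n) - 1 + n), con)
  writeLines(c(sprintf("POINT_DATA %d", 2 * n), "SCALARS radius float 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(c(sg$radius0, sg$radius), digits = 7, trim = TRUE), con)
  invisible(path)
}

#' Write the waveform as a two-column CSV
#'
#' @param waveform a `dpi_waveform`.
#' @param path output CSV path (columns `t_s`, `Q_Lmin`).
#' @param n number of samples.
#' @return the path, invisibly.
#' @export
write_waveform_csv <- function(waveform, path, n = 301) {
  t <- seq(0, if (is.finite(waveform$duration)) waveform$duration else 1,
           length.out = n)
  write.csv(data.frame(t_s = t, Q_Lmin = waveform_flow(waveform, t)), path,
            row.names = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the sweep configuration scalars, the seed and the package
#' version as JSON; a re-run from the manifest's seed and configuration
#' reproduces the outputs byte-for-byte.
#'
#' @param sweep a `fiber_sweep`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(sweep, path) {
  cf <- sweep$config
  manifest <- list(
    package = "fiberdep",
    version = as.character(packageVersion("fiberdep")),
    seed = cf$seed,
    d_p_um = cf$d_p * 1e6,
    AR = cf$AR,
    n_per_group = cf$n_per_group,
    rho_p = cf$rho_p,
    waveform = cf$waveform[c("tidal_volume", "peak_flow", "duration",
                             "rise_time", "bolus")],
    lobar_split = as.list(unclass(cf$split)),
    air = unclass(cf$air),
    options = cf$options,
    handoff = sweep$handoff
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a sweep configuration from a YAML file
#'
#' Recognized blocks: `sweep` (d_p_um, ar, n_per_group, seed, rho_p),
#' `waveform` (tidal_volume_L, peak_flow_Lmin, duration_s, rise_time_s,
#' bolus_start_s, bolus_end_s), `lobar_fractions` (LU, LL, RU, RM, RL),
#' `tree` (root_diameter_m, terminal_diameter_m, n_levels,
#' branch_angle_deg, length_over_diameter, gravity_vector), `upper`
#' (inlet_diameter_m, constriction_ratio, bend_angle_deg, gravity_vector),
#' and `tracking` (mode, dt_max, courant, lift).  Missing blocks fall back
#' to package defaults.
#'
#' @param path YAML file path.
#' @return a [sweep_config()].
#' @export
read_sweep_config <- function(path) {
  y <- yaml::read_yaml(path)
  wf <- y$waveform %||% list()
  waveform <- make_dpi_waveform(
    tidal_volume = wf$tidal_volume_L %||% 2.95,
    peak_flow = wf$peak_flow_Lmin %||% 90,
    duration = wf$duration_s %||% 3,
    rise_time = wf$rise_time_s %||% 0.4,
    bolus = c(wf$bolus_start_s %||% 0.45, wf$bolus_end_s %||% 0.6)
  )
  tb <- y$tree %||% list()
  tree <- build_bronchial_tree(
    root_diameter = tb$root_diameter_m %||% 2.45e-3,
    terminal_diameter = tb$terminal_diameter_m %||% 0.5e-3,
    n_bifurcation_levels = tb$n_levels %||% 9,
    branching_angle = tb$branch_angle_deg %||% 35,
    length_to_diameter = tb$length_over_diameter %||% 3.5,
    gravity = unlist(tb$gravity_vector) %||% c(0, 0, 1)
  )
  ub <- y$upper %||% list()
  upper <- build_upper_surrogate(
    inlet_diameter = ub$inlet_diameter_m %||% 0.02,
    constriction_ratio = ub$constriction_ratio %||% 0.5,
    bend_angle = ub$bend_angle_deg %||% 90,
    gravity = unlist(ub$gravity_vector) %||% c(0, -1, 0)
  )
  lf <- y$lobar_fractions
  split <- if (is.null(lf)) lobar_split() else do.call(lobar_split, lf)
  tk <- y$tracking %||% list()
  options <- track_options(
    mode = tk$mode %||% "desk",
    dt_max = tk$dt_max %||% 1e-3,
    courant = tk$courant %||% 0.1,
    lift = tk$lift %||% TRUE
  )
  sw <- y$sweep %||% list()
  sweep_config(
    d_p = (unlist(sw$d_p_um) %||% c(1:7, 10, 20)) * 1e-6,
    AR = unlist(sw$ar) %||% c(1, 3, 10, 30),
    n_per_group = sw$n_per_group %||% 3000,
    seed = sw$seed %||% 1,
    rho_p = sw$rho_p %||% 1000,
    waveform = waveform, upper = upper, tree = tree, split = split,
    options = options
  )
}
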