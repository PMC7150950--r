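# Deposition detection, classification, accounting, and analytic
# benchmarks.

#' Fiber-wall contact query
#'
#' A fiber is modelled for contact purposes as the axial segment
#' `[x - b_p p, x + b_p p]` of radius `a_p`: contact occurs when the
#' minimum wall distance over sample points along the segment (tips
#' included, spacing `a_p / 2`, at most 64 points) is `<= a_p`.  Spheres
#' (`AR = 1`) reduce to center distance `<= radius`.  This makes
#' interception orientation-dependent: a fiber pointing at the wall
#' contacts it while the same fiber lying parallel does not.
#'
#' @param x fiber center position (length 3).
#' @param p orientation unit vector.
#' @param spec a [fiber_spec()].
#' @param domain an `airway_domain`.
#' @return list: `contact` (logical), `position` (contact sample point),
#'   `center_wall_dist` (signed wall distance of the center).
#' @export
contact_query <- function(x, p, spec, domain) {
  wd_c <- wall_distance(domain, x)
  if (spec$AR <= 1 + 1e-12) {
    return(list(contact = wd_c <= spec$a_p, position = x,
                center_wall_dist = wd_c))
  }
  m <- min(64, max(3, ceiling(2 * spec$b_p / (spec$a_p / 2)) + 1))
  off <- seq(-spec$b_p, spec$b_p, length.out = m)
  pts <- matrix(rep(x, each = m), m, 3) + outer(off, p)
  wd <- wall_distance(domain, pts)
  k <- which.min(wd)
  list(contact = wd[k] <= spec$a_p, position = pts[k, ],
       center_wall_dist = wd_c)
}

#' Classify a deposition mechanism
#'
#' Diagnostic labels, not physics: a contact with the fiber center more
#' than `a_p` from the wall (tip-only contact) is "interception"; else
#' "sedimentation" when the gravity-aligned velocity component exceeds
#' `sed_fraction` of the total speed, and "impaction" otherwise.
#'
#' @param velocity particle velocity at contact (length 3).
#' @param gravity gravity unit vector.
#' @param center_wall_dist signed wall distance of the fiber center (m).
#' @param a_p fiber minor semi-axis (m).
#' @param sed_fraction sedimentation threshold (default 0.5).
#' @return one of "interception", "sedimentation", "impaction".
#' @export
classify_mechanism <- function(velocity, gravity, center_wall_dist, a_p,
                               sed_fraction = 0.5) {
  if (center_wall_dist > a_p) return("interception")
  sp <- sqrt(sum(velocity^2))
  if (sp > 0 && sum(velocity * gravity) > sed_fraction * sp) {
    "sedimentation"
  } else {
    "impaction"
  }
}

#' Particle conservation ledger
#'
#' Integer accounting of particle fates per group: at any time,
#' injected = airborne + deposited + exited.
#'
#' @param groups character vector of group identifiers.
#' @return ledger object.
#' @export
new_ledger <- function(groups = "all") {
  z <- rep(0L, length(groups))
  structure(list(
    counts = data.frame(
      group = as.character(groups), injected = z, airborne = z,
      deposited = z, exited = z, stringsAsFactors = FALSE
    ),
    deposited_by = list(), exited_by = list(),
    seen = character(0)
  ), class = "conservation_ledger")
}

#' Update the conservation ledger
#'
#' @param ledger a [new_ledger()].
#' @param event "inject", "deposit" or "exit".
#' @param group group identifier.
#' @param n number of particles (default 1).
#' @param where region (deposition) or outlet (exit) label.
#' @param id optional particle identifier; a repeated deposit/exit of the
#'   same id signals a status violation.
#' @return the updated ledger.
#' @export
ledger_update <- function(ledger, event, group, n = 1L, where = NA, id = NULL) {
  i <- match(group, ledger$counts$group)
  if (is.na(i)) stop("unknown group: ", group)
  cc <- ledger$counts
  if (event == "inject") {
    cc$injected[i] <- cc$injected[i] + n
    cc$airborne[i] <- cc$airborne[i] + n
  } else {
    if (!is.null(id)) {
      key <- paste0(group, "#", id)
      if (key %in% ledger$seen) {
        stop("status violation: particle ", id, " already terminal")
      }
      ledger$seen <- c(ledger$seen, key)
    }
    if (cc$airborne[i] < n) stop("status violation: not enough airborne")
    cc$airborne[i] <- cc$airborne[i] - n
    if (event == "deposit") {
      cc$deposited[i] <- cc$deposited[i] + n
      if (!is.na(where)) {
        k <- paste0(group, ":", where)
        ledger$deposited_by[[k]] <-
          (ledger$deposited_by[[k]] %||% 0L) + n
      }
    } else if (event == "exit") {
      cc$exited[i] <- cc$exited[i] + n
      if (!is.na(where)) {
        k <- paste0(group, ":", where)
        ledger$exited_by[[k]] <- (ledger$exited_by[[k]] %||% 0L) + n
      }
    } else {
      stop("unknown event: ", event)
    }
  }
  ledger$counts <- cc
  ledger
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check ledger conservation
#'
#' @param ledger a [new_ledger()].
#' @return TRUE invisibly; stops if conservation is violated.
#' @export
ledger_check <- function(ledger) {
  cc <- ledger$counts
  bad <- cc$injected != cc$airborne + cc$deposited + cc$exited
  if (any(bad)) {
    stop("conservation violated for group(s): ",
         paste(cc$group[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.conservation_ledger <- function(x, ...) {
  cat("<conservation_ledger>\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Deposition dispersion index
#'
#' For each deposited particle, the number of other deposited particles
#' within a Euclidean neighborhood radius (self excluded).  Low counts
#' indicate well-dispersed deposition; high counts indicate hot spots.
#' Conventional radii: 10 mm in the upper domain, 5 mm in the bronchial
#' tree.
#'
#' @param positions n x 3 matrix of deposited positions (m).
#' @param radius neighborhood radius (m).
#' @return integer vector of neighbor counts.
#' @export
dispersion_index <- function(positions, radius) {
  stopifnot(radius > 0)
  pts <- if (is.matrix(positions)) positions else matrix(positions, ncol = 3)
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  counts <- integer(n)
  r2 <- radius^2
  chunk <- 512L
  s2 <- rowSums(pts^2)
  for (i0 in seq(1, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    d2 <- outer(s2[i0:i1], s2, "+") - 2 * pts[i0:i1, , drop = FALSE] %*% t(pts)
    counts[i0:i1] <- rowSums(d2 <= r2) - 1L
  }
  counts
}

#' Deposition efficiency
#'
#' Fraction of the particles entering a domain that deposit there:
#' `DE = n_deposited / n_entered`.  A zero denominator is undefined and is
#' signalled distinctly from `DE = 0` (returns `NaN` with a warning).
#'
#' @param n_deposited,n_entered integer counts.
#' @return fraction in `[0, 1]`, or `NaN` when `n_entered == 0`.
#' @export
deposition_efficiency <- function(n_deposited, n_entered) {
  if (n_entered == 0) {
    warning("deposition efficiency undefined: no particles entered")
    return(NaN)
  }
  stopifnot(n_deposited >= 0, n_deposited <= n_entered)
  n_deposited / n_entered
}

#' Gravitational deposition efficiency in laminar tube flow
#'
#' Closed-form deposition efficiency of settling particles carried by
#' steady Poiseuille flow through a horizontal circular tube (flux-weighted
#' inlet concentration, no axial diffusion):
#' `eta = (2/pi) (2 k sqrt(1 - k^(2/3)) - k^(1/3) sqrt(1 - k^(2/3)) +
#' asin(k^(1/3)))` with `k = 3 v_s L / (8 u_bar R)` clamped to 1 (complete
#' deposition).  Used as the analytic benchmark for the Monte-Carlo
#' sedimentation validation.
#'
#' @param v_s settling (terminal) speed (m/s).
#' @param length,radius tube dimensions (m).
#' @param u_mean mean flow speed (m/s).
#' @return deposition efficiency in `[0, 1]`.
#' @export
pich_deposition_efficiency <- function(v_s, length, radius, u_mean) {
  k <- pmin(1, 3 * v_s * length / (8 * u_mean * radius))
  (2 / pi) * (2 * k * sqrt(1 - k^(2 / 3)) -
                k^(1 / 3) * sqrt(1 - k^(2 / 3)) + asin(k^(1 / 3)))
}
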