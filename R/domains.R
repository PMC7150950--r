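# Synthetic airway domains.
#
# A domain is a union of straight tube segments (origin, unit axis, length,
# radius) plus connectivity.  A segment may begin with a conical taper from
# an entrance radius (normally the parent's radius) down/up to its nominal
# radius over `taper_len`; this smooth transition is what lets the analytic
# flow field steer particles through constrictions and into daughter
# branches instead of depositing them on fictitious junction faces, while
# keeping a genuine carina wedge between siblings for inertial impaction.
# Walls are the lateral (capsule-blended) surfaces; inlet and terminal
# outlet planes are open.  All units SI, right-handed frame.

seg_df <- function(origin, dir, length, radius, radius0 = radius,
                   taper_len = radius, generation = 1L, region = "seg",
                   parent = NA_integer_, outlet = NA_character_) {
  data.frame(
    x0 = origin[1], y0 = origin[2], z0 = origin[3],
    dx = dir[1], dy = dir[2], dz = dir[3],
    length = length, radius = radius, radius0 = radius0,
    taper_len = taper_len, generation = generation,
    region = region, parent = parent, outlet = outlet,
    stringsAsFactors = FALSE
  )
}

unit <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# any unit vector perpendicular to d
perp_vector <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(ref - sum(ref * d) * d)
}

new_domain <- function(segments, children, gravity, type) {
  rownames(segments) <- NULL
  structure(list(
    segments = segments,
    children = children,
    gravity = unit(gravity),
    type = type
  ), class = c(paste0("airway_", type), "airway_domain"))
}

#' Build a symmetric dichotomous bronchial tree
#'
#' Constructs an idealized symmetric bifurcating bronchial tree.  Per-level
#' diameters follow a geometric progression solved so that the first level
#' equals `root_diameter` and the deepest equals `terminal_diameter`
#' (defaults 2.45 mm down to 0.5 mm, i.e. conducting-airway generations
#' 7--16: 10 airway levels joined by 9 bifurcation stages).  Branch length
#' is `length_to_diameter * diameter`; children leave the parent axis at
#' `branching_angle` (half-angle), with the branching plane rotated 90
#' degrees at successive levels to fill 3D space, and open with a conical
#' entrance taper from the parent radius over one own-diameter.
#'
#' @param root_diameter inlet diameter (m).
#' @param terminal_diameter deepest-level diameter (m).
#' @param n_bifurcation_levels number of bifurcation stages (>= 1); the
#'   tree has `n_bifurcation_levels + 1` airway levels and
#'   `2^n_bifurcation_levels` terminal segments.
#' @param branching_angle half-angle between child and parent axis (deg).
#' @param length_to_diameter branch length over branch diameter.
#' @param gravity gravity unit vector; default `+z` (the tree axis, i.e.
#'   gravity initially streamwise).
#' @param root_generation integer label of the root level (default 7).
#' @param root_origin,root_direction position and unit axis of the inlet.
#' @param check_overlap verify that non-adjacent segments do not intersect
#'   (signals "degenerate geometry" if they do).
#' @return An object of class `airway_tree` / `airway_domain`.
#' @export
#' @examples
#' tr <- build_bronchial_tree()
#' range(tr$segments$radius) * 2 # 0.5e-3 ... 2.45e-3
build_bronchial_tree <- function(root_diameter = 2.45e-3,
                                 terminal_diameter = 0.5e-3,
                                 n_bifurcation_levels = 9,
                                 branching_angle = 35,
                                 length_to_diameter = 3.5,
                                 gravity = c(0, 0, 1),
                                 root_generation = 7L,
                                 root_origin = c(0, 0, 0),
                                 root_direction = c(0, 0, 1),
                                 check_overlap = TRUE) {
  stopifnot(
    terminal_diameter > 0, root_diameter >= terminal_diameter,
    n_bifurcation_levels >= 1, length_to_diameter > 0,
    branching_angle > 0, branching_angle < 90
  )
  ratio <- (terminal_diameter / root_diameter)^(1 / n_bifurcation_levels)
  diam <- root_diameter * ratio^(0:n_bifurcation_levels)
  th <- branching_angle * pi / 180

  segs <- list()
  kids <- list()
  d0 <- unit(root_direction)
  queue <- list(list(o = root_origin, d = d0, u = perp_vector(d0),
                     lvl = 0L, parent = NA_integer_))
  i <- 0L
  while (length(queue) > 0) {
    nd <- queue[[1]]; queue <- queue[-1]
    i <- i + 1L
    lvl <- nd$lvl
    D <- diam[lvl + 1L]
    L <- length_to_diameter * D
    terminal <- lvl == n_bifurcation_levels
    r_entry <- if (is.na(nd$parent)) D / 2 else diam[lvl] / 2
    segs[[i]] <- seg_df(nd$o, nd$d, L, D / 2,
      radius0 = r_entry, taper_len = min(D, L / 2),
      generation = root_generation + lvl,
      region = paste0("g", root_generation + lvl),
      parent = nd$parent,
      outlet = if (terminal) sprintf("t%d", i) else NA_character_
    )
    kids[[i]] <- integer(0)
    if (!is.na(nd$parent)) kids[[nd$parent]] <- c(kids[[nd$parent]], i)
    if (!terminal) {
      tip <- nd$o + L * nd$d
      for (s in c(1, -1)) {
        dc <- unit(cos(th) * nd$d + s * sin(th) * nd$u)
        uc <- unit(cross3(nd$d, nd$u))
        queue <- c(queue, list(list(o = tip, d = dc, u = uc,
                                    lvl = lvl + 1L, parent = i)))
      }
    }
  }
  segments <- do.call(rbind, segs)
  dom <- new_domain(segments, kids, gravity, "tree")
  if (check_overlap) check_no_overlap(dom)
  dom
}

#' Build a generic upper-airway surrogate
#'
#' A deliberately generic conducting-airway analog standing in for the
#' mouth--throat and proximal airways: a horizontal inlet tube, a tapered
#' constriction (larynx analog producing a jet-like acceleration under
#' Poiseuille scaling), a bend turning the airway downward, a vertical
#' trachea analog, and five outlet branches labeled with the lobar tokens
#' LU, LL, RU, RM, RL.  No anatomical fidelity is claimed.
#'
#' @param inlet_diameter mouth-opening diameter (m).
#' @param constriction_ratio constriction diameter / inlet diameter, in
#'   (0, 1).
#' @param bend_angle total turn of the bend (degrees), split over two
#'   segments.
#' @param lobar_map character vector of 5 outlet labels; must contain each
#'   of "LU", "LL", "RU", "RM", "RL" exactly once.
#' @param gravity gravity unit vector; default `-y`.
#' @return An object of class `airway_upper` / `airway_domain`.
#' @export
#' @examples
#' up <- build_upper_surrogate()
#' up$segments$radius[up$segments$region == "throat"] # 5 mm
build_upper_surrogate <- function(inlet_diameter = 0.02,
                                  constriction_ratio = 0.5,
                                  bend_angle = 90,
                                  lobar_map = c("LU", "LL", "RU", "RM", "RL"),
                                  gravity = c(0, -1, 0)) {
  stopifnot(
    inlet_diameter > 0, constriction_ratio > 0, constriction_ratio < 1,
    bend_angle > 0, bend_angle <= 120
  )
  if (length(lobar_map) != 5 ||
      !setequal(lobar_map, c("LU", "LL", "RU", "RM", "RL")) ||
      anyDuplicated(lobar_map) > 0) {
    stop("lobar_map must contain each of LU, LL, RU, RM, RL exactly once")
  }
  D0 <- inlet_diameter
  Dc <- constriction_ratio * D0
  Dt <- 0.8 * D0 # trachea analog
  Dl <- 0.5 * D0 # lobar branches
  segs <- list()
  kids <- list()
  o <- c(0, 0, 0)
  add <- function(dirv, L, D, region, parent, D_entry = D,
                  outlet = NA_character_) {
    i <- length(segs) + 1L
    segs[[i]] <<- seg_df(o, dirv, L, D / 2, radius0 = D_entry / 2,
                         taper_len = min(D, L / 2), generation = i,
                         region = region, parent = parent, outlet = outlet)
    kids[[i]] <<- integer(0)
    if (!is.na(parent)) kids[[parent]] <<- c(kids[[parent]], i)
    i
  }
  dx <- c(1, 0, 0)
  i1 <- add(dx, 4 * D0, D0, "mouth", NA_integer_); o <- o + 4 * D0 * dx
  i2 <- add(dx, 2.5 * Dc, Dc, "throat", i1, D_entry = D0); o <- o + 2.5 * Dc * dx
  a1 <- -bend_angle / 2 * pi / 180
  a2 <- -bend_angle * pi / 180
  d1 <- c(cos(a1), sin(a1), 0)
  d2 <- c(cos(a2), sin(a2), 0)
  Lb <- 1.5 * Dt
  i3 <- add(d1, Lb, Dt, "bend", i2, D_entry = Dc); o <- o + Lb * d1
  i4 <- add(d2, Lb, Dt, "bend", i3); o <- o + Lb * d2
  i5 <- add(d2, 5 * Dt, Dt, "trachea", i4); o <- o + 5 * Dt * d2
  # five outlet branches fanned around the trachea axis
  tilt <- 40 * pi / 180
  e1 <- perp_vector(d2)
  e2 <- cross3(d2, e1)
  trachea_tip <- o
  for (k in seq_len(5)) {
    phi <- 2 * pi * (k - 1) / 5
    dk <- unit(cos(tilt) * d2 + sin(tilt) * (cos(phi) * e1 + sin(phi) * e2))
    o <- trachea_tip
    add(dk, 4 * Dl, Dl, lobar_map[k], i5, D_entry = Dt, outlet = lobar_map[k])
  }
  segments <- do.call(rbind, segs)
  new_domain(segments, kids, gravity, "upper")
}

#' Straight-tube validation domain
#'
#' A single straight tube segment, used for analytic validation cases
#' (gravitational deposition in laminar tube flow, interception in
#' wall-bounded shear).
#'
#' @param length,radius tube dimensions (m).
#' @param direction unit axis vector.
#' @param gravity gravity unit vector.
#' @return An object of class `airway_tube` / `airway_domain`.
#' @export
straight_tube <- function(length = 0.1, radius = 1e-3,
                          direction = c(1, 0, 0), gravity = c(0, 0, -1)) {
  stopifnot(length > 0, radius > 0)
  segments <- seg_df(c(0, 0, 0), unit(direction), length, radius,
                     generation = 1L, region = "tube", outlet = "end")
  new_domain(segments, list(integer(0)), gravity, "tube")
}

# local radius of a (possibly tapered) segment at axial coordinate s
segment_radius_at <- function(seg, s) {
  w <- pmax(0, 1 - s / seg$taper_len)
  seg$radius + (seg$radius0 - seg$radius) * w
}

# per-segment signed inside distance for a matrix of points (n x 3):
# distance to the lateral (capsule/cone) surface, positive inside.
segment_inside_distance <- function(seg, pts) {
  rel <- cbind(pts[, 1] - seg$x0, pts[, 2] - seg$y0, pts[, 3] - seg$z0)
  s <- rel[, 1] * seg$dx + rel[, 2] * seg$dy + rel[, 3] * seg$dz
  sc <- pmin(pmax(s, 0), seg$length)
  ax <- cbind(rel[, 1] - sc * seg$dx, rel[, 2] - sc * seg$dy,
              rel[, 3] - sc * seg$dz)
  Reff <- segment_radius_at(seg, sc)
  slope <- ifelse(sc < seg$taper_len,
                  (seg$radius - seg$radius0) / seg$taper_len, 0)
  (Reff - sqrt(rowSums(ax^2))) / sqrt(1 + slope^2)
}

#' Signed wall distance
#'
#' Signed distance from points to the nearest airway wall: positive inside
#' the lumen, non-positive outside.  Computed as the maximum over segments
#' of the analytic point-to-axis (capsule/cone) distance, exact for
#' cylindrical segments.
#'
#' @param domain an `airway_domain`.
#' @param points numeric vector (length 3) or n x 3 matrix of positions (m).
#' @return numeric vector of signed distances (m).
#' @export
#' @examples
#' wall_distance(straight_tube(radius = 1e-3), c(0.05, 0, 0)) # 1e-3
wall_distance <- function(domain, points) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  sg <- domain$segments
  best <- rep(-Inf, nrow(pts))
  for (j in seq_len(nrow(sg))) {
    best <- pmax(best, segment_inside_distance(sg[j, ], pts))
  }
  best
}

#' Locate the region containing a point
#'
#' Deterministically assigns each point a region label: the region tag of
#' the containing segment (the segment with the largest inside distance),
#' `"exited:<outlet>"` for points beyond a terminal outlet plane, or
#' `"outside"` otherwise.
#'
#' @inheritParams wall_distance
#' @return character vector of region tags.
#' @export
locate_region <- function(domain, points) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  sg <- domain$segments
  n <- nrow(pts)
  best <- rep(-Inf, n)
  lab <- rep("outside", n)
  for (j in seq_len(nrow(sg))) {
    d <- segment_inside_distance(sg[j, ], pts)
    take <- d > best & d > 0
    best[take] <- d[take]
    lab[take] <- sg$region[j]
  }
  for (j in which(!is.na(sg$outlet))) {
    seg <- sg[j, ]
    rel <- cbind(pts[, 1] - seg$x0, pts[, 2] - seg$y0, pts[, 3] - seg$z0)
    s <- rel[, 1] * seg$dx + rel[, 2] * seg$dy + rel[, 3] * seg$dz
    ax2 <- rowSums(rel^2) - s^2
    past <- s > seg$length & ax2 <= seg$radius^2
    lab[past] <- paste0("exited:", seg$outlet)
  }
  lab
}

#' Uniform Cartesian seed grid on the inlet disc
#'
#' Particle release points: a uniform Cartesian lattice in the inlet plane
#' clipped to the inlet disc, with the lattice pitch solved so the clipped
#' count falls within 10% of `n_points`.  The seed orientation is the
#' streamwise (inlet axis) direction, reflecting the assumed immediate flow
#' alignment of inhaled fibers.
#'
#' @param domain an `airway_domain`.
#' @param n_points requested number of seed points (>= 1).
#' @return list with `points` (m x 3 matrix), `orientation` (unit vector)
#'   and `segment` (root segment index); class `seed_grid`.
#' @export
inlet_seed_grid <- function(domain, n_points) {
  stopifnot(n_points >= 1)
  root <- which(is.na(domain$segments$parent))[1]
  seg <- domain$segments[root, ]
  d <- c(seg$dx, seg$dy, seg$dz)
  o <- c(seg$x0, seg$y0, seg$z0)
  R <- seg$radius0
  e1 <- perp_vector(d)
  e2 <- cross3(d, e1)
  if (n_points == 1) {
    pts <- matrix(o, ncol = 3)
  } else {
    h <- R * sqrt(pi / n_points)
    count_at <- function(h) {
      k <- ceiling(R / h)
      g <- expand.grid(a = (-k:k) * h, b = (-k:k) * h)
      sum(g$a^2 + g$b^2 < (R * (1 - 1e-9))^2)
    }
    for (it in 1:40) {
      cnt <- count_at(h)
      if (abs(cnt - n_points) <= 0.1 * n_points) break
      h <- h * sqrt(cnt / n_points)
    }
    k <- ceiling(R / h)
    g <- expand.grid(a = (-k:k) * h, b = (-k:k) * h)
    g <- g[g$a^2 + g$b^2 < (R * (1 - 1e-9))^2, , drop = FALSE]
    pts <- t(o + outer(e1, g$a) + outer(e2, g$b))
  }
  structure(list(points = pts, orientation = d, segment = root),
            class = "seed_grid")
}

#' Total lumen volume of a domain
#'
#' Sum of the segment volumes (cone frustum + cylinder for tapered
#' segments); used for the inter-domain hand-off delay.
#'
#' @param domain an `airway_domain`.
#' @return volume (m^3).
#' @export
domain_volume <- function(domain) {
  sg <- domain$segments
  taper <- pmin(sg$taper_len, sg$length)
  v_cone <- pi / 3 * taper * (sg$radius0^2 + sg$radius0 * sg$radius +
                                sg$radius^2)
  v_cyl <- pi * sg$radius^2 * (sg$length - taper)
  sum(v_cone + v_cyl)
}

# exact minimum distance between two finite 3D segments
segment_segment_distance <- function(p1, d1, L1, p2, d2, L2) {
  r <- p1 - p2
  b <- sum(d1 * d2)
  d <- sum(d1 * r); e <- sum(d2 * r)
  den <- 1 - b * b
  if (den > 1e-12) {
    s <- (b * e - d) / den
  } else {
    s <- -d
  }
  s <- min(max(s, 0), L1)
  t <- sum(d2 * (p1 + s * d1 - p2))
  t <- min(max(t, 0), L2)
  s <- sum(d1 * (p2 + t * d2 - p1))
  s <- min(max(s, 0), L1)
  sqrt(sum((p1 + s * d1 - p2 - t * d2)^2))
}

# Signal "degenerate geometry" if branches interfere where it matters
# dynamically: siblings must separate at the tips, and segment pairs within
# graph distance <= 4 (the neighborhood particles can actually interact
# with) must not intersect.  Remote branches of a deep straight-segment
# tree may interpenetrate in the embedding; the tree is intrinsically
# defined and transport/contact are evaluated on the local branch
# neighborhood, so that has no dynamical effect (see the methods
# vignette).
check_no_overlap <- function(domain, max_graph_dist = 4L) {
  sg <- domain$segments
  n <- nrow(sg)
  P <- as.matrix(sg[, c("x0", "y0", "z0")])
  Dm <- as.matrix(sg[, c("dx", "dy", "dz")])
  mid <- P + Dm * sg$length / 2
  bound <- sg$length / 2 + pmax(sg$radius, sg$radius0)
  for (i in seq_len(n)) {
    ch <- domain$children[[i]]
    if (length(ch) == 2) {
      a <- ch[1]; b <- ch[2]
      tipa <- P[a, ] + Dm[a, ] * sg$length[a]
      tipb <- P[b, ] + Dm[b, ] * sg$length[b]
      if (sqrt(sum((tipa - tipb)^2)) < sg$radius[a] + sg$radius[b]) {
        stop("degenerate geometry: sibling branches do not separate")
      }
    }
  }
  ancestors <- function(i) {
    a <- integer(0)
    while (!is.na(sg$parent[i])) {
      i <- sg$parent[i]
      a <- c(a, i)
    }
    a
  }
  graph_dist <- function(i, j) {
    ai <- c(i, ancestors(i)); aj <- c(j, ancestors(j))
    common <- intersect(ai, aj)
    if (length(common) == 0) return(Inf)
    lca <- common[1]
    (match(lca, ai) - 1L) + (match(lca, aj) - 1L)
  }
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    near <- sqrt(rowSums((mid[js, , drop = FALSE] -
                            matrix(mid[i, ], length(js), 3,
                                   byrow = TRUE))^2)) < bound[i] + bound[js]
    for (j in js[near]) {
      gd <- graph_dist(i, j)
      if (gd <= 2L || gd > max_graph_dist) next # parent/child/sibling ok
      dd <- segment_segment_distance(P[i, ], Dm[i, ], sg$length[i],
                                     P[j, ], Dm[j, ], sg$length[j])
      if (dd < sg$radius[i] + sg$radius[j]) {
        stop(sprintf("degenerate geometry: segments %d and %d intersect",
                     i, j))
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.airway_domain <- function(x, ...) {
  sg <- x$segments
  cat(sprintf("<%s> %d segments, %d terminal outlet(s)\n",
              class(x)[1], nrow(sg), sum(!is.na(sg$outlet))))
  cat(sprintf("  diameters %.3g .. %.3g mm, total lumen volume %.3g mL\n",
              2e3 * min(sg$radius), 2e3 * max(sg$radius),
              1e6 * domain_volume(x)))
  cat(sprintf("  gravity direction (%.2g, %.2g, %.2g)\n",
              x$gravity[1], x$gravity[2], x$gravity[3]))
  invisible(x)
}
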