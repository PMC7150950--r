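test_that("bronchial tree diameters follow the solved geometric progression", {
  tr <- build_bronchial_tree(check_overlap = FALSE)
  sg <- tr$segments
  d_by_gen <- vapply(sort(unique(sg$generation)), function(g) {
    2 * sg$radius[sg$generation == g][1]
  }, numeric(1))
  expect_equal(length(d_by_gen), 10) # generations 7..16
  expect_equal(d_by_gen[1], 2.45e-3)
  expect_equal(d_by_gen[10], 0.5e-3)
  ratio <- (0.5 / 2.45)^(1 / 9)
  for (i in 1:9) {
    expect_equal(d_by_gen[i + 1] / d_by_gen[i], ratio, tolerance = 1e-12)
  }
  # terminal count = 2^levels; every non-terminal has exactly two children
  expect_equal(sum(!is.na(sg$outlet)), 2^9)
  n_kids <- lengths(tr$children)
  expect_true(all(n_kids[is.na(sg$outlet)] == 2))
  expect_true(all(n_kids[!is.na(sg$outlet)] == 0))
})

test_that("degenerate tree parameters are rejected", {
  # equal endpoints and one level: both generations the same diameter
  tr <- build_bronchial_tree(1e-3, 1e-3, 1, check_overlap = FALSE)
  expect_equal(unique(2 * tr$segments$radius), 1e-3)
  # a near-zero branching angle cannot separate siblings
  expect_error(build_bronchial_tree(branching_angle = 1),
               "degenerate geometry")
  expect_error(build_bronchial_tree(root_diameter = 0.5e-3,
                                    terminal_diameter = 2.45e-3))
})

test_that("upper surrogate applies the constriction ratio and validates the lobar map", {
  up <- build_upper_surrogate(0.02, 0.5, 30)
  expect_equal(up$segments$radius[up$segments$region == "throat"], 5e-3)
  out <- up$segments$outlet[!is.na(up$segments$outlet)]
  expect_setequal(out, c("LU", "LL", "RU", "RM", "RL"))
  expect_error(
    build_upper_surrogate(lobar_map = c("LU", "LL", "RU", "RU", "RL")),
    "lobar_map"
  )
  expect_error(build_upper_surrogate(constriction_ratio = 1.2))
})

test_that("constriction accelerates the mean flow by the inverse area ratio", {
  up <- build_upper_surrogate(0.02, 0.5)
  fld <- poiseuille_field(up, steady_flow(30), lobar_split())
  # centerline samples in the fully-developed parts of mouth and throat
  sg <- up$segments
  mouth_end <- c(0.06, 0, 0)
  throat <- sg[sg$region == "throat", ]
  s_cyl <- throat$taper_len + 0.55 * (throat$length - throat$taper_len)
  throat_pt <- c(throat$x0 + s_cyl, 0, 0)
  u_m <- field_velocity(fld, mouth_end, 0)[1, 1]
  u_t <- field_velocity(fld, throat_pt, 0)[1, 1]
  expect_equal(u_t / u_m, 4, tolerance = 1e-9)
})

test_that("wall distance matches a brute-force per-segment oracle", {
  tr <- build_bronchial_tree(n_bifurcation_levels = 3, check_overlap = FALSE)
  sg <- tr$segments
  # independent brute force: max over all segments of the capsule/cone
  # signed distance, recomputed from first principles
  brute <- function(p) {
    best <- -Inf
    for (j in seq_len(nrow(sg))) {
      o <- c(sg$x0[j], sg$y0[j], sg$z0[j])
      d <- c(sg$dx[j], sg$dy[j], sg$dz[j])
      s <- sum((p - o) * d)
      sc <- min(max(s, 0), sg$length[j])
      w <- max(0, 1 - sc / sg$taper_len[j])
      R <- sg$radius[j] + (sg$radius0[j] - sg$radius[j]) * w
      slope <- if (sc < sg$taper_len[j]) {
        (sg$radius[j] - sg$radius0[j]) / sg$taper_len[j]
      } else 0
      di <- (R - sqrt(sum((p - o - sc * d)^2))) / sqrt(1 + slope^2)
      best <- max(best, di)
    }
    best
  }
  set.seed(11)
  lim <- apply(as.matrix(sg[, c("x0", "y0", "z0")]), 2, range)
  pts <- cbind(runif(100, lim[1, 1] - 5e-3, lim[2, 1] + 5e-3),
               runif(100, lim[1, 2] - 5e-3, lim[2, 2] + 5e-3),
               runif(100, lim[1, 3], lim[2, 3] + 1e-2))
  wd <- wall_distance(tr, pts)
  for (i in 1:100) expect_equal(wd[i], brute(pts[i, ]), tolerance = 1e-12)
  # axis point of a tube: distance = radius; wall point: 0
  tube <- straight_tube(length = 0.1, radius = 1e-3)
  expect_equal(wall_distance(tube, c(0.05, 0, 0)), 1e-3)
  expect_equal(wall_distance(tube, c(0.05, 1e-3, 0)), 0)
})

test_that("wall distance is continuous along rays inside a segment", {
  tr <- build_bronchial_tree(n_bifurcation_levels = 2, check_overlap = FALSE)
  sg <- tr$segments[1, ]
  h <- 1e-5
  s <- seq(0.1 * sg$length, 0.9 * sg$length, by = h)
  ray <- cbind(sg$x0 + 0.3 * sg$radius, sg$y0, sg$z0 + s) # along the root
  wd <- wall_distance(tr, ray)
  expect_true(all(abs(diff(wd)) <= 2 * h))
})

test_that("locate_region assigns points like a brute-force containing-segment search", {
  tr <- build_bronchial_tree(n_bifurcation_levels = 3, check_overlap = FALSE)
  sg <- tr$segments
  # random interior points: sample a segment, a radial position well inside
  set.seed(3)
  pts <- t(vapply(sample(nrow(sg), 100, replace = TRUE), function(j) {
    o <- c(sg$x0[j], sg$y0[j], sg$z0[j])
    d <- c(sg$dx[j], sg$dy[j], sg$dz[j])
    e1 <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- unit(e1 - sum(e1 * d) * d)
    s <- runif(1, 0.55, 0.95) * sg$length[j] # in the cylindrical part
    r <- runif(1, 0, 0.6) * sg$radius[j]
    o + s * d + r * e1
  }, numeric(3)))
  lab <- locate_region(tr, pts)
  # brute force: per-point argmax of the per-segment inside distance
  for (i in 1:100) {
    di <- vapply(seq_len(nrow(sg)), function(j) {
      fiberdep:::segment_inside_distance(sg[j, ], pts[i, , drop = FALSE])
    }, numeric(1))
    expect_equal(lab[i], sg$region[which.max(di)])
  }
  # inlet-plane point maps to the root region; beyond a terminal outlet
  # plane maps to exited
  expect_equal(locate_region(tr, c(0, 0, 0)), "g7")
  term <- sg[!is.na(sg$outlet), ][1, ]
  beyond <- c(term$x0, term$y0, term$z0) +
    (term$length + 1e-4) * c(term$dx, term$dy, term$dz)
  expect_equal(locate_region(tr, beyond), paste0("exited:", term$outlet))
})

test_that("inlet seed grids are uniform lattices clipped to the disc", {
  up <- build_upper_surrogate()
  g1 <- inlet_seed_grid(up, 1)
  expect_equal(nrow(g1$points), 1)
  expect_equal(g1$points[1, ], c(0, 0, 0))
  expect_equal(g1$orientation, c(1, 0, 0))
  for (n in c(100, 500, 3000)) {
    g <- inlet_seed_grid(up, n)
    m <- nrow(g$points)
    expect_lte(abs(m - n), 0.1 * n)
    expect_true(all(wall_distance(up, g$points) > 0))
    # uniform Cartesian: in-plane coordinates live on a single pitch
    yz <- g$points[, 2:3]
    py <- diff(sort(unique(round(yz[, 1], 12))))
    expect_lt(max(py) - min(py), 1e-9)
  }
})

test_that("lumen volume accounts for conical entrance tapers", {
  tube <- straight_tube(length = 0.1, radius = 1e-3)
  expect_equal(domain_volume(tube), pi * 1e-6 * 0.1, tolerance = 1e-12)
  up <- build_upper_surrogate()
  # bounded by the all-nominal and all-entry cylinder volumes
  sg <- up$segments
  expect_gt(domain_volume(up), sum(pi * pmin(sg$radius, sg$radius0)^2 * sg$length))
  expect_lt(domain_volume(up), sum(pi * pmax(sg$radius, sg$radius0)^2 * sg$length))
})
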