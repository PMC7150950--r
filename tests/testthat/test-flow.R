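test_that("DPI waveform satisfies the printed volume, peak and boundary constraints", {
  wf <- make_dpi_waveform(2.95, 90, 3, 0.4)
  expect_equal(waveform_flow(wf, 0), 0)
  expect_equal(waveform_flow(wf, 3), 0)
  # plateau end solved in closed form: t_h = 2 TV/P - T + t_r with
  # P = 1.5 L/s -> 4/3 s (independent arithmetic)
  expect_equal(wf$t_h, 2 * 2.95 / 1.5 - 3 + 0.4, tolerance = 1e-12)
  expect_equal(wf$t_h, 4 / 3, tolerance = 1e-12)
  # adaptive quadrature of Q(t) equals the tidal volume to 1e-6 relative
  vol <- integrate(function(t) waveform_flow(wf, t) / 60, 0, 3,
                   rel.tol = 1e-9)$value
  expect_equal(vol, 2.95, tolerance = 1e-6)
  # the maximum equals the peak flow exactly on the plateau
  tt <- seq(0, 3, length.out = 2001)
  expect_equal(max(waveform_flow(wf, tt)), 90)
  expect_equal(waveform_flow(wf, (0.4 + 4 / 3) / 2), 90)
  # infeasible configurations are signalled
  expect_error(make_dpi_waveform(10, 90, 3), "infeasible")
  expect_error(make_dpi_waveform(0.1, 90, 3), "infeasible")
})

test_that("lobar split validates and propagates to outlet flux fractions", {
  sp <- lobar_split()
  expect_equal(sum(sp), 100)
  expect_error(lobar_split(LU = 20), "sum")
  expect_error(lobar_split(LU = -5, LL = 51), "positive")
  up <- build_upper_surrogate()
  fld <- poiseuille_field(up, steady_flow(60), sp)
  sg <- up$segments
  out <- which(!is.na(sg$outlet))
  expect_equal(setNames(fld$frac[out] * 100, sg$outlet[out])[names(sp)],
               setNames(as.numeric(sp), names(sp)))
  # interior segments carry the descendant sum: the root carries all flow
  root <- which(is.na(sg$parent))
  expect_equal(fld$frac[root], 1, tolerance = 1e-12)
})

test_that("flux is conserved at every bifurcation and across sections", {
  tr <- build_bronchial_tree(n_bifurcation_levels = 4, check_overlap = FALSE)
  wf <- make_dpi_waveform()
  fld <- poiseuille_field(tr, wf)
  sg <- tr$segments
  for (i in seq_len(nrow(sg))) {
    kids <- tr$children[[i]]
    if (length(kids) == 2) {
      expect_equal(sum(fld$frac[kids]), fld$frac[i], tolerance = 1e-10)
    }
  }
  # numeric flux through a mid-segment cross-section equals the assigned
  # share of Q(t) (polar quadrature of the axial profile)
  t_at <- 1 # plateau
  Q <- waveform_flow(wf, t_at) / 60000
  for (j in c(1, 2, 5)) {
    o <- c(sg$x0[j], sg$y0[j], sg$z0[j])
    d <- c(sg$dx[j], sg$dy[j], sg$dz[j])
    e1 <- unit(if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
    e1 <- unit(e1 - sum(e1 * d) * d)
    e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
            d[1] * e1[2] - d[2] * e1[1])
    s_mid <- sg$taper_len[j] + 0.6 * (sg$length[j] - sg$taper_len[j])
    R <- sg$radius[j]
    nr <- 60; na <- 40
    rs <- (seq_len(nr) - 0.5) / nr * R
    as <- (seq_len(na) - 0.5) / na * 2 * pi
    flux <- 0
    for (r in rs) {
      pts <- t(vapply(as, function(a) {
        o + s_mid * d + r * (cos(a) * e1 + sin(a) * e2)
      }, numeric(3)))
      u <- field_velocity(fld, pts, t_at)
      flux <- flux + sum(u %*% d) * r * (R / nr) * (2 * pi / na)
    }
    expect_equal(flux, fld$frac[j] * Q, tolerance = 1e-3)
  }
})

test_that("the parabolic field obeys no-slip and its analytic gradient matches finite differences", {
  up <- build_upper_surrogate()
  tr <- build_bronchial_tree(n_bifurcation_levels = 3, check_overlap = FALSE)
  wf <- make_dpi_waveform()
  for (dom in list(up, tr)) {
    fld <- poiseuille_field(dom, wf, if (dom$type == "upper") lobar_split())
    sg <- dom$segments
    set.seed(5)
    # wall-adjacent points: exactly on the wall the velocity vanishes
    js <- sample(nrow(sg), 20, replace = TRUE)
    for (j in js) {
      o <- c(sg$x0[j], sg$y0[j], sg$z0[j])
      d <- c(sg$dx[j], sg$dy[j], sg$dz[j])
      e1 <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- unit(e1 - sum(e1 * d) * d)
      s <- sg$taper_len[j] + runif(1, 0.3, 0.7) * (sg$length[j] - sg$taper_len[j])
      wallpt <- o + s * d + sg$radius[j] * e1
      expect_equal(as.numeric(field_velocity(fld, wallpt, 1)), c(0, 0, 0))
    }
    # centerline velocity is twice the sectional mean in straight parts
    j <- which(is.na(sg$parent))[1]
    o <- c(sg$x0[j], sg$y0[j], sg$z0[j]); d <- c(sg$dx[j], sg$dy[j], sg$dz[j])
    mid <- o + 0.9 * sg$length[j] * d
    Q <- waveform_flow(wf, 1) / 60000 * fld$frac[j]
    ubar <- Q / (pi * sg$radius[j]^2)
    expect_equal(sum(field_velocity(fld, mid, 1) * d), 2 * ubar,
                 tolerance = 1e-9)
    # gradient vs central finite differences at 50 interior points
    pts <- t(vapply(sample(nrow(sg), 50, replace = TRUE), function(j) {
      o <- c(sg$x0[j], sg$y0[j], sg$z0[j])
      d <- c(sg$dx[j], sg$dy[j], sg$dz[j])
      e1 <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- unit(e1 - sum(e1 * d) * d)
      s <- runif(1, 0.3, 0.7) * sg$length[j]
      r <- runif(1, 0.1, 0.7) * sg$radius[j]
      o + s * d + r * e1
    }, numeric(3)))
    for (i in seq_len(nrow(pts))) {
      G <- field_gradient(fld, pts[i, ], 1)
      h <- 1e-7
      Gfd <- matrix(0, 3, 3)
      for (k in 1:3) {
        dp <- dm <- pts[i, ]
        dp[k] <- dp[k] + h; dm[k] <- dm[k] - h
        Gfd[, k] <- (field_velocity(fld, dp, 1) -
                       field_velocity(fld, dm, 1)) / (2 * h)
      }
      scale <- max(abs(G)) + 1e-12
      expect_lt(max(abs(G - Gfd)) / scale, 1e-4)
    }
  }
})

test_that("simple shear field has the exact constant gradient and spectrum", {
  sh <- simple_shear_field(10)
  expect_equal(as.numeric(field_velocity(sh, c(0, 2, 0))), c(20, 0, 0))
  G <- field_gradient(sh, c(1, 1, 1))
  expect_equal(G[1, 2], 10)
  expect_equal(sum(abs(G)), 10) # single nonzero entry
  # vorticity magnitude = rate; symmetric-part eigenvalues = +-rate/2, 0
  om <- c(G[3, 2] - G[2, 3], G[1, 3] - G[3, 1], G[2, 1] - G[1, 2])
  expect_equal(sqrt(sum(om^2)), 10)
  S <- (G + t(G)) / 2
  expect_equal(sort(eigen(S, symmetric = TRUE)$values), c(-5, 0, 5))
})

test_that("hand-off scaling and delay follow continuity arithmetic", {
  # identical domains, full flow: scale 1, delay = V / Qbar
  tube <- straight_tube(length = 0.2, radius = 5e-3)
  f1 <- poiseuille_field(tube, steady_flow(30))
  f2 <- poiseuille_field(straight_tube(length = 0.2, radius = 5e-3),
                         steady_flow(30))
  ho <- handoff_scale(f1, f2)
  expect_equal(ho$scale, 1, tolerance = 1e-9)
  expect_equal(ho$delay, domain_volume(tube) / (30 / 60000), tolerance = 1e-6)
  # downstream inlet area halved with half the flow: scale = 1
  f3 <- poiseuille_field(straight_tube(length = 0.2, radius = 5e-3 / sqrt(2)),
                         steady_flow(30), flow_scale = 0.5)
  expect_equal(handoff_scale(f1, f3)$scale, 1, tolerance = 1e-9)
  # upstream volume 0.1 L at the default DPI mean flow (0.9833 L/s):
  # delay ~ 0.102 s
  Rv <- 5e-3; Lv <- 0.1 / 1000 / (pi * Rv^2)
  up <- poiseuille_field(straight_tube(length = Lv, radius = Rv),
                         make_dpi_waveform())
  ho2 <- handoff_scale(up, f1)
  expect_equal(ho2$delay, 0.1e-3 / (2.95e-3 / 3), tolerance = 1e-6)
  expect_equal(ho2$delay, 0.1017, tolerance = 1e-3)
  # zero upstream flow is signalled
  f0 <- poiseuille_field(tube, steady_flow(0))
  expect_error(handoff_scale(f0, f1), "no flow")
})

test_that("Reynolds diagnostic decreases monotonically from the upper inlet to the tree terminals", {
  up <- build_upper_surrogate()
  tr <- build_bronchial_tree()
  wf <- make_dpi_waveform()
  uf <- poiseuille_field(up, wf, lobar_split())
  tf <- poiseuille_field(tr, wf, flow_scale = tree_inlet_scale(up, tr))
  rp <- reynolds_profile(uf, tf)
  expect_equal(nrow(rp), 11) # inlet + generations 7..16
  expect_true(all(diff(rp$Re) < 0))
  # order-of-magnitude sanity: thousands at the inlet, ones-to-tens at the
  # deepest generation
  expect_gt(rp$Re[1], 1e3)
  expect_lt(rp$Re[11], 1e2)
})
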