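# Internal marshalling of R-level objects into the plain-array form the
# C++ core consumes.

pack_waveform <- function(wf) {
  if (wf$type == "constant") {
    list(type = 1L, P = wf$peak_flow / 60000,
         tr = 0, th = 0,
         T = if (is.finite(wf$duration)) wf$duration else 1e30)
  } else {
    list(type = 0L, P = wf$peak_flow / 60000,
         tr = wf$rise_time, th = wf$t_h, T = wf$duration)
  }
}

pack_field <- function(field) {
  if (inherits(field, "shear_field")) {
    stop("shear fields are evaluated natively in R")
  }
  sg <- field$domain$segments
  list(
    seg_o = as.matrix(sg[, c("x0", "y0", "z0")]),
    seg_d = as.matrix(sg[, c("dx", "dy", "dz")]),
    len = sg$length,
    radius = sg$radius,
    radius0 = sg$radius0,
    taper = sg$taper_len,
    frac = field$frac,
    parent = as.integer(ifelse(is.na(sg$parent), -1L, sg$parent - 1L)),
    terminal = as.integer(!is.na(sg$outlet)),
    children = lapply(field$domain$children, function(k) as.integer(k - 1L)),
    waveform = pack_waveform(field$waveform),
    flow_scale = field$flow_scale,
    gravity = field$domain$gravity
  )
}

pack_fiber <- function(spec) {
  spec[c("a_p", "b_p", "AR", "d_stk", "t0", "rho_p", "mass",
         "K_par", "K_perp", "lambda")]
}
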