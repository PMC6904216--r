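# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# node-aligned planar-capacitor pair: slab boundaries coincide with grid
# nodes so trilinear interpolation reproduces the piecewise-linear profile
# exactly (kinks mid-cell would otherwise add O(spacing) error)
capacitor_pair <- function(v1 = -100, v2 = 0, slab = c(16, 44),
                           box = c(40, 40, 60), spacing = 2) {
  list(make_capacitor_grid(box = box, slab = slab, voltage = v1,
                           spacing = spacing),
       make_capacitor_grid(box = box, slab = slab, voltage = v2,
                           spacing = spacing))
}

# analytic coupling function of the capacitor: fraction of the voltage
# drop felt at height z
capacitor_f <- function(z, slab = c(16, 44)) {
  pmin(pmax((z - slab[1]) / (slab[2] - slab[1]), 0), 1)
}

# rigid rotation matrix about a coordinate axis, degrees
rot3 <- function(axis = c("x", "y", "z"), deg) {
  axis <- match.arg(axis)
  th <- deg * pi / 180
  c_ <- cos(th); s <- sin(th)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, -s, 0, s, c_), 3, 3, byrow = TRUE),
    y = matrix(c(c_, 0, s, 0, 1, 0, -s, 0, c_), 3, 3, byrow = TRUE),
    z = matrix(c(c_, -s, 0, s, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE))
}

# apply a rigid transform (rotation R then translation t) to a frame
transform_frame <- function(frame, R = diag(3), t = c(0, 0, 0)) {
  xyz <- coords(frame) %*% t(R)
  frame$x <- xyz[, 1] + t[1]
  frame$y <- xyz[, 2] + t[2]
  frame$z <- xyz[, 3] + t[3]
  frame
}

# single-atom frame at a position
lone_atom <- function(pos = c(0, 0, 0), element = "C") {
  conformation_frame(atom_id = 1L, x = pos[1], y = pos[2], z = pos[3],
                     element = element, residue_index = 1L,
                     residue_name = "LIG")
}
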