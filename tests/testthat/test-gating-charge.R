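# Coupling-function gating-charge decomposition against the analytic
# planar-capacitor oracle: f(z) = (z - z0)/(z1 - z0) clamped to [0, 1], so
# a charge q moved across the slab carries exactly q * delta(f).

slab <- c(16, 44)

# a frame of single-atom "charge carrier" residues at given z heights
charge_frame <- function(z, state = "s", ids = seq_along(z)) {
  conformation_frame(atom_id = ids, x = 20, y = 20, z = z,
                     element = "C", residue_index = seq_along(z),
                     residue_name = "ARG", atom_name = "CZ",
                     state_label = state)
}

test_that("coupling function equals the analytic capacitor profile", {
  grids <- capacitor_pair(v1 = -100, v2 = 0, slab = slab)
  z <- c(2, 16, 23, 30, 37, 44, 58)   # bulk, edges, quarter points, mid
  fr <- charge_frame(z)
  cp <- coupling_function(fr, grids)
  expect_equal(cp$f, capacitor_f(z, slab), tolerance = 1e-9)
  # midpoint is exactly 0.5, grounded bulk 0, driven bulk 1
  expect_equal(cp$f[4], 0.5)
  expect_equal(cp$f[1], 0)
  expect_equal(cp$f[7], 1)
})

test_that("coupling function rejects coincident voltages and out-of-grid atoms", {
  g <- make_capacitor_grid(slab = slab, voltage = -100)
  expect_error(coupling_function(charge_frame(30), list(g, g)),
               "distinct")
  grids <- capacitor_pair()
  expect_error(coupling_function(charge_frame(200), grids), "outside")
})

test_that("multi-grid slope recovers the capacitor profile under 1% noise", {
  volts <- seq(-200, 200, by = 50)   # nine potentials
  grids <- lapply(seq_along(volts), function(i)
    make_capacitor_grid(slab = slab, voltage = volts[i],
                        noise_sd = 0.01 * max(abs(volts)), seed = 100 + i))
  z <- seq(18, 42, by = 3)
  cp <- coupling_function(charge_frame(z), grids)
  expect_lt(max(abs(cp$f - capacitor_f(z, slab))), 0.02)
})

test_that("coupling function is gauge invariant under a voltage-independent offset field", {
  grids <- capacitor_pair(v1 = -100, v2 = 0, slab = slab)
  z <- seq(10, 50, by = 5)
  f0 <- coupling_function(charge_frame(z), grids)$f
  offset <- function(g) {
    d <- dim(g$values)
    zs <- g$origin[3] + (seq_len(d[3]) - 1) * g$spacing[3]
    bump <- 25 * sin(zs / 7)   # arbitrary static field, same in both grids
    g$values <- g$values + array(rep(bump, each = d[1] * d[2]), dim = d)
    g
  }
  f1 <- coupling_function(charge_frame(z), lapply(grids, offset))$f
  expect_equal(f1, f0, tolerance = 1e-9)
})

test_that("single moving charge: Qj follows Eq-1 arithmetic and the capacitor oracle", {
  grids <- capacitor_pair(v1 = -100, v2 = 0, slab = slab)
  # fr = 0.2 and fa = 0.9 by placing the charge at the matching heights
  z_r <- slab[1] + 0.2 * diff(slab)
  z_a <- slab[1] + 0.9 * diff(slab)
  fr_r <- charge_frame(z_r, "resting")
  fr_a <- charge_frame(z_a, "activated")
  q <- c("1" = 1)
  tab <- per_residue_charge(fr_r, fr_a,
                            coupling_function(fr_r, grids),
                            coupling_function(fr_a, grids), q)
  expect_equal(tab$Q, 0.7, tolerance = 1e-9)
  expect_equal(attr(tab, "net_per_vsd"), 0.7, tolerance = 1e-9)

  # full transfer across the slab carries exactly q
  fr_r2 <- charge_frame(2, "resting")
  fr_a2 <- charge_frame(58, "activated")
  tab2 <- per_residue_charge(fr_r2, fr_a2,
                             coupling_function(fr_r2, grids),
                             coupling_function(fr_a2, grids), q)
  expect_equal(tab2$Q, 1.0, tolerance = 1e-6)

  # static charge, identical fields: exactly zero
  tab0 <- per_residue_charge(fr_r, fr_r,
                             coupling_function(fr_r, grids),
                             coupling_function(fr_r, grids), q)
  expect_equal(tab0$Q, 0)
})

test_that("per-residue charges match the analytic displacement oracle for many residues", {
  grids <- capacitor_pair(v1 = -100, v2 = 0, slab = slab)
  set.seed(9)
  n <- 12
  z_r <- runif(n, 10, 50)
  z_a <- runif(n, 10, 50)
  q <- runif(n, -1, 1)
  names(q) <- seq_len(n)
  fr_r <- charge_frame(z_r, "resting")
  fr_a <- charge_frame(z_a, "activated")
  tab <- per_residue_charge(fr_r, fr_a,
                            coupling_function(fr_r, grids),
                            coupling_function(fr_a, grids), q)
  oracle <- unname(q) * (capacitor_f(z_a, slab) - capacitor_f(z_r, slab))
  expect_equal(tab$Q, oracle, tolerance = 1e-6)
  # additivity: total of any disjoint split equals the net
  expect_equal(sum(tab$Q[1:5]) + sum(tab$Q[6:n]),
               attr(tab, "net_per_vsd"), tolerance = 1e-12)
  # cumulative curve ends at the net charge
  expect_equal(tail(attr(tab, "cumulative"), 1), attr(tab, "net_per_vsd"))
})

test_that("a static charge gains charge iff the field rearranges between states", {
  # state-dependent fields: the slab narrows upon activation, so f changes
  # at a fixed position even though the charge does not move
  grids_r <- capacitor_pair(v1 = -100, v2 = 0, slab = c(16, 44))
  grids_a <- capacitor_pair(v1 = -100, v2 = 0, slab = c(24, 44))
  z <- 30   # inside both slabs
  fr <- charge_frame(z, "resting")
  fa <- charge_frame(z, "activated")
  q <- c("1" = -1)
  tab <- per_residue_charge(fr, fa,
                            coupling_function(fr, grids_r),
                            coupling_function(fa, grids_a), q)
  expected <- -1 * ((z - 24) / 20 - (z - 16) / 28)
  expect_equal(tab$Q, expected, tolerance = 1e-9)
  expect_gt(abs(tab$Q), 0.05)   # nonzero despite zero displacement
  # same static charge in a state-independent field: exactly zero
  tab0 <- per_residue_charge(fr, fa,
                             coupling_function(fr, grids_r),
                             coupling_function(fa, grids_r), q)
  expect_equal(tab0$Q, 0)
})

test_that("per_residue_charge validates topology and charge coverage", {
  grids <- capacitor_pair()
  fr <- charge_frame(c(20, 30))
  fa <- charge_frame(30)
  expect_error(per_residue_charge(fr, fa,
                                  coupling_function(fr, grids),
                                  coupling_function(fa, grids),
                                  c("1" = 1, "2" = 1)),
               "topology")
  fa2 <- charge_frame(c(25, 35))
  expect_error(per_residue_charge(fr, fa2,
                                  coupling_function(fr, grids),
                                  coupling_function(fa2, grids),
                                  c("1" = 1)),
               "missing partial charge")
})

test_that("aggregation over conformations: means, standard errors, per-channel total", {
  mk <- function(net) {
    grids <- capacitor_pair()
    fr <- charge_frame(slab[1], "r")
    fa <- charge_frame(slab[1] + net * diff(slab), "a")
    per_residue_charge(fr, fa, coupling_function(fr, grids),
                       coupling_function(fa, grids), c("1" = 1))
  }
  one <- aggregate_charge(list(mk(0.5)), subunits = 4)
  expect_equal(one$per_channel, 4 * 0.5, tolerance = 1e-9)
  expect_true(is.na(one$net_stderr))   # undefined for a single table

  five <- aggregate_charge(rep(list(mk(0.5)), 5), subunits = 4)
  expect_equal(five$net_stderr, 0)

  mix <- aggregate_charge(list(mk(0.3), mk(0.4), mk(0.5)), subunits = 4)
  expect_equal(mix$net_per_vsd, 0.4, tolerance = 1e-9)
  # closed-form standard error oracle: sd/sqrt(n)
  expect_equal(mix$net_stderr, sd(c(0.3, 0.4, 0.5)) / sqrt(3),
               tolerance = 1e-9)
})
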