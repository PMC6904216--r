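# Torsions, helicity, axes, bend angles, RMSD, contacts, hydration.

test_that("torsions of an ideal helix match the builder inputs within 1 degree", {
  h <- make_helix(15, phi = -57, psi = -47)
  tor <- compute_torsions(h)
  inner <- tor[tor$defined, ]
  expect_true(all(abs(inner$phi + 57) < 1))
  expect_true(all(abs(inner$psi + 47) < 1))
  # termini are flagged, not dropped
  expect_false(tor$defined[1])
  expect_false(tor$defined[nrow(tor)])
  expect_equal(nrow(tor), 15)
})

test_that("a 3-residue chain has undefined torsions only at its termini", {
  h <- make_helix(3)
  tor <- compute_torsions(h)
  expect_equal(tor$defined, c(FALSE, TRUE, FALSE))
})

test_that("mirror reflection flips the sign of both torsions", {
  h <- make_helix(10)
  mir <- h
  mir$x <- -mir$x   # improper transformation
  t0 <- compute_torsions(h)
  t1 <- compute_torsions(mir)
  d <- t0$defined
  expect_equal(t1$phi[d], -t0$phi[d], tolerance = 1e-9)
  expect_equal(t1$psi[d], -t0$psi[d], tolerance = 1e-9)
})

test_that("helicity closed forms are exact and the score stays in [0, 1]", {
  expect_equal(helicity(-57, -47), 1)
  expect_equal(helicity(-57 + 180, -47 + 180), 0)
  expect_equal(helicity(-57 + 90, -47), 0.5)   # (1+0)(1+1)/4
  expect_true(is.na(helicity(NA_real_, -47)))
  # property: bounded for arbitrary angles
  set.seed(42)
  phi <- runif(500, -180, 180); psi <- runif(500, -180, 180)
  hp <- helicity(phi, psi)
  expect_true(all(hp >= 0 & hp <= 1))
  # maximum only at the reference torsions (mod 360)
  expect_equal(helicity(-57 + 360, -47 - 360), 1)
})

test_that("principal axis of a straight helix is the z axis and rotates with the frame", {
  h <- make_helix(20)
  sel <- residue_selection("A", 1:20)
  ax <- principal_axis(h, sel)
  expect_equal(abs(ax[3]), 1, tolerance = 1e-3)
  R <- rot3("x", 30)
  hr <- transform_frame(h, R = R)
  ax_r <- principal_axis(hr, sel, normal = as.numeric(R %*% c(0, 0, 1)))
  expect_equal(ax_r, as.numeric(R %*% ax), tolerance = 1e-6)
})

test_that("isotropic point clouds have no principal axis", {
  # vertices of a regular octahedron: exactly isotropic covariance
  oct <- conformation_frame(
    atom_id = 1:6,
    x = c(1, -1, 0, 0, 0, 0), y = c(0, 0, 1, -1, 0, 0),
    z = c(0, 0, 0, 0, 1, -1),
    element = "C", residue_index = 1:6, residue_name = "ALA",
    atom_name = "CA")
  expect_error(principal_axis(oct, residue_selection("A", 1:6)),
               "degenerate")
})

test_that("bend angle: parallel 0, perpendicular 90, hinge ground truth within 3 degrees", {
  # exactly straight Calpha line: parallel and perpendicular are exact
  line <- make_helix(10, phi = NULL, radius = 0)
  sel <- residue_selection("A", 1:10)
  expect_equal(bend_angle(line, sel, c(0, 0, 1)), 0, tolerance = 1e-9)
  expect_equal(bend_angle(line, sel, c(1, 0, 0)), 90, tolerance = 1e-9)

  # short segments of a real helix wobble around the global axis by a few
  # degrees: a straight helix reads as nearly parallel
  h <- make_helix(30)
  upper <- residue_selection("A", 1:14)
  lower <- residue_selection("A", 16:30)
  ax <- principal_axis(h, upper)
  expect_lt(bend_angle(h, lower, ax), 5)

  hh90 <- make_hinged_helix(30, 15, 90)
  ax_u <- principal_axis(hh90, upper)
  expect_equal(bend_angle(hh90, lower, ax_u), 90, tolerance = 3)

  hh <- make_hinged_helix(30, 15, 80)
  ax_u <- principal_axis(hh, upper)
  expect_equal(bend_angle(hh, lower, ax_u), 80, tolerance = 3)
  expect_error(bend_angle(h, residue_selection("A", 1:3), ax), ">= 4")
})

test_that("bend angle is invariant under joint rigid motion", {
  hh <- make_hinged_helix(30, 15, 60)
  upper <- residue_selection("A", 1:14)
  lower <- residue_selection("A", 16:30)
  ax <- principal_axis(hh, upper)
  a0 <- bend_angle(hh, lower, ax)
  R <- rot3("y", 50) %*% rot3("z", 10)
  hh2 <- transform_frame(hh, R = R, t = c(3, -2, 8))
  expect_equal(bend_angle(hh2, lower, as.numeric(R %*% ax)), a0,
               tolerance = 1e-6)
})

test_that("RMSD closed forms and superposition invariance", {
  h <- make_helix(25)
  sel <- residue_selection("A", 1:25)
  expect_equal(rmsd_to_reference(h, h, sel), 0)
  hr <- transform_frame(h, R = rot3("z", 73), t = c(5, 5, -3))
  expect_equal(rmsd_to_reference(hr, h, sel, superpose = TRUE), 0,
               tolerance = 1e-6)
  # one atom displaced 2 A among N = 100 atoms, no superposition: 2/sqrt(100)
  h100 <- make_helix(100)
  sel100 <- residue_selection("A", 1:100)
  h100b <- h100
  i <- which(h100b$atom_name == "CA")[50]
  h100b$x[i] <- h100b$x[i] + 2
  expect_equal(rmsd_to_reference(h100b, h100, sel100, superpose = FALSE),
               2 / sqrt(100))
  # mismatched atom sets are reported
  h_miss <- h[-(3:6), ]
  class(h_miss) <- class(h)
  expect_error(rmsd_to_reference(h_miss, h, sel), "missing residue")
})

test_that("contact persistence equals the brute-force fraction of contact frames", {
  # two CA atoms at controlled distances over 10 frames: 7 within 4.5 A
  dists <- c(rep(3, 7), rep(8, 3))
  frames <- lapply(dists, function(d)
    conformation_frame(atom_id = 1:2, x = c(0, d), y = 0, z = 0,
                       element = "C", residue_index = c(1L, 2L),
                       residue_name = "ALA", atom_name = "CA"))
  gA <- residue_selection("A", 1)
  gB <- residue_selection("A", 2)
  cp <- contact_persistence(frames, gA, gB, cutoff = 4.5)
  expect_equal(cp$persistence, 0.7)
  # always in contact
  cp1 <- contact_persistence(frames[1:7], gA, gB, cutoff = 4.5)
  expect_equal(cp1$persistence, 1.0)
  # never in contact: absent by default, persistence 0 when kept
  cp0 <- contact_persistence(frames[8:10], gA, gB, cutoff = 4.5)
  expect_equal(nrow(cp0), 0)
  cp0k <- contact_persistence(frames[8:10], gA, gB, cutoff = 4.5,
                              keep_zero = TRUE)
  expect_equal(cp0k$persistence, 0)
  expect_error(contact_persistence(frames, gA, gB, cutoff = -1),
               "positive")
})

test_that("hydration profile counts waters per bin and summarises percentiles", {
  mf <- membrane_frame(slab_bounds = c(0, 30))
  # 10 waters in one 3 A bin
  w <- conformation_frame(atom_id = 1:10, x = runif(10, 0, 5),
                          y = runif(10, 0, 5), z = rep(1.5, 10),
                          element = "O", residue_index = 1:10,
                          residue_name = "HOH", chain_id = "W",
                          atom_name = "OH2")
  hp <- hydration_profile(list(w), mframe = mf, bin_width = 3,
                          zlim = c(0, 30))
  expect_equal(sum(hp$counts), 10)
  expect_equal(hp$counts[1, 1], 10)
  # identical frames: all percentiles equal the single-frame count
  hp5 <- hydration_profile(rep(list(w), 5), mframe = mf, bin_width = 3,
                           zlim = c(0, 30))
  expect_true(all(hp5$percentiles[, 1] == 10))
  expect_error(hydration_profile(list(), mframe = mf), "no frames")
})

test_that("hydration bins match a direct histogram oracle and the median a sort oracle", {
  wb <- make_water_box(c(0, 10), c(0, 10), c(0, 30), n_waters = 300,
                       seed = 5)
  mf <- membrane_frame(slab_bounds = c(0, 30))
  hp <- hydration_profile(list(wb), mframe = mf, bin_width = 3,
                          zlim = c(0, 30))
  oracle <- hist(wb$z, breaks = seq(0, 30, 3), plot = FALSE)$counts
  expect_equal(hp$counts[1, ], oracle)
  expect_true(all(abs(hp$counts[1, ] - 30) < 20))  # roughly uniform
  # median percentile equals a naive sort-based median across frames
  frames <- lapply(1:7, function(s)
    make_water_box(c(0, 10), c(0, 10), c(0, 30), 100, seed = s))
  hp7 <- hydration_profile(frames, mframe = mf, bin_width = 3,
                           zlim = c(0, 30))
  naive_median <- apply(hp7$counts, 2, function(v) sort(v)[4])
  expect_equal(unname(hp7$percentiles["p50", ]), as.numeric(naive_median))
  # percentiles are monotone across the listed order
  expect_true(all(diff(hp7$percentiles[, 1]) >= 0))
})
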