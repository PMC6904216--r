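# Synthetic-data generators. Each generator produces one input class of
# the analysis stages with known ground truth, so that every
# generator/analyzer pair closes: analysis(generate(theta)) recovers theta
# within a documented tolerance. All randomness is controlled by an
# explicit seed and the caller's RNG state is restored on exit.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# NeRF placement: position of atom D bonded to C, with bond length r,
# angle theta at C (B-C-D) and dihedral chi about B-C (A-B-C-D), degrees.
.place_atom <- function(a, b, c_, r, theta, chi) {
  d2r <- pi / 180
  # negated azimuth gives the IUPAC sign convention for dihedral(a,b,c,d)
  theta <- theta * d2r; chi <- -chi * d2r
  bc <- c_ - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d_local <- r * c(-cos(theta), sin(theta) * cos(chi),
                   sin(theta) * sin(chi))
  c_ + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# standard backbone internal coordinates (Engh & Huber averages)
.BB <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
            a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
            a_ca_c_o = 120.5)

#' Build an ideal polyalanine helix
#'
#' Constructs a backbone (N, CA, C, O) chain with every residue at the
#' stated (phi, psi) torsions via natural-extension-reference-frame
#' placement with standard bond geometry, then aligns the helix axis with
#' +z (the membrane normal) and centres it. With the default alpha-helical
#' torsions the Calpha rise is ~1.5 A/residue; passing `rise` rescales the
#' structure along z so the mean Calpha rise matches exactly (a small
#' affine distortion of the torsions, negligible near the natural rise).
#'
#' Passing `phi = NULL` instead builds a parametric Calpha-only helix of
#' radius `radius` (default 2.3 A) from `rise` and `twist` directly
#' (useful for pure axis-fitting fixtures; no torsions are defined there;
#' `radius = 0` gives an exactly straight line of Calphas).
#'
#' @param n_residues Number of residues (>= 2).
#' @param rise Target Calpha rise per residue along z, A (default `NULL`:
#'   natural rise of the torsions; parametric mode default 1.5).
#' @param twist Helical twist per residue, degrees; parametric mode only
#'   (default 100).
#' @param phi,psi Backbone torsions, degrees (defaults -57 / -47).
#' @param radius Calpha radius for the parametric mode, A (default 2.3).
#' @param chain_id Chain label.
#' @param state_label Frame tag.
#' @return A [conformation_frame()].
#' @export
make_helix <- function(n_residues, rise = NULL, twist = 100,
                       phi = -57, psi = -47, radius = 2.3,
                       chain_id = "A", state_label = "helix") {
  if (is.null(phi)) {
    if (is.null(rise)) rise <- 1.5
    i <- seq_len(n_residues) - 1
    ang <- i * twist * pi / 180
    return(conformation_frame(
      atom_id = seq_len(n_residues),
      x = radius * cos(ang), y = radius * sin(ang), z = i * rise,
      element = "C", residue_index = seq_len(n_residues),
      residue_name = "ALA", chain_id = chain_id, atom_name = "CA",
      state_label = state_label))
  }
  if (n_residues < 2) stop("need >= 2 residues")
  if (!is.finite(phi) || !is.finite(psi) ||
      abs(phi) > 180 || abs(psi) > 180)
    stop("invalid torsions: phi/psi must be finite angles in [-180, 180]")
  g <- .BB
  # seed triad for residue 1
  N <- matrix(NA_real_, n_residues, 3)
  CA <- matrix(NA_real_, n_residues, 3)
  C <- matrix(NA_real_, n_residues, 3)
  O <- matrix(NA_real_, n_residues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_residues - 1)) {
    N[i + 1, ] <- .place_atom(N[i, ], CA[i, ], C[i, ],
                              g$b_c_n, g$a_ca_c_n, psi)
    CA[i + 1, ] <- .place_atom(CA[i, ], C[i, ], N[i + 1, ],
                               g$b_n_ca, g$a_c_n_ca, 180)
    C[i + 1, ] <- .place_atom(C[i, ], N[i + 1, ], CA[i + 1, ],
                              g$b_ca_c, g$a_n_ca_c, phi)
  }
  for (i in seq_len(n_residues)) {
    psi_i <- psi  # carbonyl O is anti to the next amide N
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ],
                          g$b_c_o, g$a_ca_c_o, psi_i + 180)
  }
  xyz <- rbind(N, CA, C, O)
  ord <- as.vector(t(matrix(seq_len(4 * n_residues), n_residues, 4)))
  # interleave per residue: N, CA, C, O
  xyz <- xyz[ord, , drop = FALSE]
  atom_names <- rep(c("N", "CA", "C", "O"), n_residues)
  elements <- rep(c("N", "C", "C", "O"), n_residues)
  resid <- rep(seq_len(n_residues), each = 4)
  # align helix axis with +z using the Calpha principal axis
  ca_idx <- which(atom_names == "CA")
  axis <- eigen(stats::cov(xyz[ca_idx, , drop = FALSE]),
                symmetric = TRUE)$vectors[, 1]
  if (axis[3] < 0) axis <- -axis
  # rotation taking `axis` to z (Rodrigues)
  v <- c(axis[2] * 1 - axis[3] * 0,
         axis[3] * 0 - axis[1] * 1,
         axis[1] * 0 - axis[2] * 0)  # axis x z
  s <- sqrt(sum(v^2)); cth <- axis[3]
  if (s < 1e-12) {
    R <- diag(3)
  } else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
                 3, 3, byrow = TRUE)
    R <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, colMeans(xyz[ca_idx, , drop = FALSE]))
  # orient the chain N->C toward +z by a proper rotation (180 deg about x)
  # so that rise is positive and chirality is preserved
  if (xyz[ca_idx[n_residues], 3] < xyz[ca_idx[1], 3]) {
    xyz[, 2] <- -xyz[, 2]
    xyz[, 3] <- -xyz[, 3]
  }
  if (!is.null(rise)) {
    ca_z <- xyz[ca_idx, 3]
    natural <- (ca_z[n_residues] - ca_z[1]) / (n_residues - 1)
    xyz[, 3] <- xyz[, 3] * rise / natural
  }
  conformation_frame(
    atom_id = seq_len(nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = elements, residue_index = resid,
    residue_name = "ALA", chain_id = chain_id, atom_name = atom_names,
    state_label = state_label)
}

#' Build a hinged helix
#'
#' Starts from [make_helix()] aligned with +z and rotates the lower
#' (C-terminal) segment, residues `hinge_residue..n`, by `bend` degrees
#' about an in-membrane-plane axis (y) through the hinge Calpha. This is
#' the fixture for bend-angle recovery: the stated bend is the ground
#' truth for the angle between the sub-helix axes.
#'
#' @param n_residues Number of residues.
#' @param hinge_residue Hinge position, strictly inside the chain.
#' @param bend Bend angle in degrees, in \[0, 180\].
#' @param ... Passed to [make_helix()].
#' @return A [conformation_frame()].
#' @export
make_hinged_helix <- function(n_residues, hinge_residue, bend, ...) {
  if (!(hinge_residue > 1 && hinge_residue < n_residues))
    stop("hinge_residue must satisfy 1 < hinge < n_residues")
  if (bend < 0 || bend > 180) stop("bend must be in [0, 180] degrees")
  fr <- make_helix(n_residues, ...)
  pivot_row <- which(fr$residue_index == hinge_residue &
                       fr$atom_name == "CA")
  if (length(pivot_row) == 0)  # parametric Calpha-only mode
    pivot_row <- which(fr$residue_index == hinge_residue)
  pivot <- as.numeric(coords(fr)[pivot_row[1], ])
  th <- bend * pi / 180
  # rotation about y through the pivot
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
              3, 3, byrow = TRUE)
  move <- fr$residue_index >= hinge_residue
  xyz <- coords(fr)
  xyz[move, ] <- sweep(sweep(xyz[move, , drop = FALSE], 2, pivot) %*% t(R),
                       2, pivot, "+")
  fr$x <- xyz[, 1]; fr$y <- xyz[, 2]; fr$z <- xyz[, 3]
  attr(fr, "hinge") <- list(residue = hinge_residue, bend = bend)
  fr
}

#' Planar-capacitor potential grid
#'
#' The textbook transmembrane field: potential 0 on the grounded side
#' (below `slab[1]`), `voltage` on the driven side (above `slab[2]`), and
#' linear in z across the slab — what an ideal low-dielectric membrane
#' between conducting electrolytes produces. Optional additive Gaussian
#' noise emulates the statistical error of potential maps averaged over
#' short simulation windows.
#'
#' @param box Length-3 box dimensions in A; the grid spans
#'   `[0, box]` on each axis.
#' @param slab Length-2, `(z0, z1)` slab bounds in A with `z0 < z1`.
#' @param voltage Applied voltage Vm, mV.
#' @param spacing Grid spacing in A (default 2).
#' @param noise_sd Additive Gaussian noise on every node, mV (default 0).
#' @param seed RNG seed for the noise.
#' @return A [potential_grid()].
#' @export
make_capacitor_grid <- function(box = c(40, 40, 60), slab = c(15, 45),
                                voltage = 100, spacing = 2,
                                noise_sd = 0, seed = NULL) {
  if (!(slab[1] < slab[2])) stop("degenerate slab: need z0 < z1")
  if (slab[1] < 0 || slab[2] > box[3])
    stop("slab must lie inside the box")
  nx <- floor(box[1] / spacing) + 1
  ny <- floor(box[2] / spacing) + 1
  nz <- floor(box[3] / spacing) + 1
  z <- (seq_len(nz) - 1) * spacing
  prof <- pmin(pmax((z - slab[1]) / (slab[2] - slab[1]), 0), 1) * voltage
  vals <- array(rep(prof, each = nx * ny), dim = c(nx, ny, nz))
  if (noise_sd > 0)
    vals <- vals + with_seed(seed, array(stats::rnorm(length(vals),
                                                      sd = noise_sd),
                                         dim = dim(vals)))
  grid <- potential_grid(origin = c(0, 0, 0),
                         spacing = rep(spacing, 3),
                         values = vals, applied_voltage = voltage)
  attr(grid, "slab") <- slab
  grid
}

#' Random water box
#'
#' Uniformly placed water oxygens inside an axis-aligned box, one
#' single-atom HOH residue each; the fixture for hydration profiling.
#'
#' @param xlim,ylim,zlim Length-2 numeric extents in A.
#' @param n_waters Number of waters.
#' @param seed RNG seed.
#' @return A [conformation_frame()].
#' @export
make_water_box <- function(xlim = c(0, 30), ylim = c(0, 30),
                           zlim = c(0, 30), n_waters = 300, seed = NULL) {
  if (n_waters < 1) stop("n_waters must be >= 1")
  xyz <- with_seed(seed, cbind(stats::runif(n_waters, xlim[1], xlim[2]),
                               stats::runif(n_waters, ylim[1], ylim[2]),
                               stats::runif(n_waters, zlim[1], zlim[2])))
  conformation_frame(
    atom_id = seq_len(n_waters),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = "O", residue_index = seq_len(n_waters),
    residue_name = "HOH", chain_id = "W", atom_name = "OH2",
    state_label = "water")
}

#' Noisy relative-Po curve from known double-Boltzmann truth
#'
#' @param params Named vector/list with `A1 O1 V1 k1 A2 O2 V2 k2`.
#' @param voltages Voltages, mV (default -150..50 in 10 mV steps, the
#'   standard test-pulse range).
#' @param noise_sd Additive Gaussian noise on Po (default 0).
#' @param seed RNG seed.
#' @return data.frame with `voltage_mV`, `relative_po` and attribute
#'   `truth`.
#' @export
make_pov_curve <- function(params, voltages = seq(-150, 50, by = 10),
                           noise_sd = 0, seed = NULL) {
  y <- double_boltzmann(voltages, params)
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(y), sd = noise_sd))
  out <- data.frame(voltage_mV = voltages, relative_po = y)
  attr(out, "truth") <- params
  out
}

#' Crooks-consistent Gaussian work samples
#'
#' Draws forward work from `N(dG + beta sigma^2 / 2, sigma^2)` and reverse
#' work from `N(-dG + beta sigma^2 / 2, sigma^2)`: the unique Gaussian
#' pair satisfying Crooks' fluctuation theorem for a true free-energy
#' difference `dG`, so BAR on these samples is unbiased by construction.
#'
#' @param dG_true True free-energy difference, kcal/mol.
#' @param sigma Work standard deviation, kcal/mol (default 1).
#' @param n Samples per direction (default 5000).
#' @param temperature K (default 300).
#' @param seed RNG seed.
#' @param window_index Window label.
#' @return A [work_samples()] object with attribute `truth`.
#' @export
make_work_samples <- function(dG_true, sigma = 1, n = 5000,
                              temperature = 300, seed = NULL,
                              window_index = 1L) {
  if (sigma <= 0 || n < 1) stop("invalid sigma or n")
  beta <- 1 / (KB_KCAL * temperature)
  shift <- beta * sigma^2 / 2
  w <- with_seed(seed, list(
    f = stats::rnorm(n, mean = dG_true + shift, sd = sigma),
    r = stats::rnorm(n, mean = -dG_true + shift, sd = sigma)))
  ws <- work_samples(w$f, w$r, temperature = temperature,
                     window_index = window_index)
  attr(ws, "truth") <- dG_true
  ws
}

#' Simulated MTSET modification time course
#'
#' Peak current versus cumulative exposure following
#' `I(t) = Iinf + (I0 - Iinf) exp(-k2nd * C * t)` with multiplicative
#' Gaussian noise on each measurement (default 2%), emulating run-to-run
#' variation of peak-current readings.
#'
#' @param k2nd_true True second-order rate, 1/(M s).
#' @param concentration Reagent concentration, mol/L (default 1e-3, the
#'   standard 1 mM application).
#' @param timepoints Either a count (points spread over 4 time constants)
#'   or an explicit vector of cumulative exposure times, s.
#' @param noise_frac Multiplicative noise fraction (default 0.02).
#' @param I0,Iinf Initial and plateau currents (defaults 1 and 2.5:
#'   potentiation, as for reagents that increase open probability).
#' @param seed RNG seed.
#' @return data.frame with `cum_exposure_s`, `peak_current` and attribute
#'   `truth` (list with `k2nd`, `tau`, `concentration`).
#' @export
make_modification_course <- function(k2nd_true, concentration = 1e-3,
                                     timepoints = 20, noise_frac = 0.02,
                                     I0 = 1, Iinf = 2.5, seed = NULL) {
  if (k2nd_true <= 0 || concentration <= 0)
    stop("rate and concentration must be positive")
  tau <- 1 / (k2nd_true * concentration)
  t <- if (length(timepoints) == 1)
    seq(0, 4 * tau, length.out = timepoints) else as.numeric(timepoints)
  y <- Iinf + (I0 - Iinf) * exp(-t / tau)
  if (noise_frac > 0)
    y <- y * with_seed(seed, 1 + stats::rnorm(length(y), sd = noise_frac))
  out <- data.frame(cum_exposure_s = t, peak_current = y)
  attr(out, "truth") <- list(k2nd = k2nd_true, tau = tau,
                             concentration = concentration)
  out
}

#' Alignment with controlled column conservation
#'
#' Emits `n_sequences` sequences: at column j each sequence carries the
#' consensus residue with probability `per_column_conservation[j]` and
#' otherwise a residue drawn uniformly from the other 19. Conservation 1
#' gives zero-entropy columns; conservation 1/20 gives (in expectation)
#' maximum-entropy columns.
#'
#' @param consensus_seq Consensus as a single string, e.g. `"LRVIRLVRVF"`.
#' @param per_column_conservation Scalar or per-column vector in
#'   \[0, 1\].
#' @param n_sequences Number of sequences (default 50).
#' @param seed RNG seed.
#' @return Named character vector of aligned sequences (an in-memory MSA
#'   accepted by [column_stats()] and [consensus()]).
#' @export
make_msa <- function(consensus_seq, per_column_conservation = 0.9,
                     n_sequences = 50, seed = NULL) {
  cols <- strsplit(toupper(consensus_seq), "")[[1]]
  if (!all(cols %in% .AA20)) stop("consensus must use the 20 residue codes")
  L <- length(cols)
  cons <- rep_len(per_column_conservation, L)
  if (any(cons < 0 | cons > 1)) stop("conservation must be in [0, 1]")
  with_seed(seed, {
    seqs <- vapply(seq_len(n_sequences), function(s) {
      chars <- vapply(seq_len(L), function(j) {
        if (stats::runif(1) <= cons[j]) cols[j]
        else sample(setdiff(.AA20, cols[j]), 1)
      }, character(1))
      paste(chars, collapse = "")
    }, character(1))
    names(seqs) <- sprintf("synthetic_seq_%03d", seq_len(n_sequences))
    seqs
  })
}

#' Write an in-memory alignment as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    writeLines(unname(seqs[i]), con)
  }
  invisible(path)
}
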