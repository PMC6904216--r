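# Helix geometry: backbone torsions, the per-residue helicity metric,
# principal axes, bend angles, Kabsch RMSD and contact persistence.

# signed dihedral of four points, degrees in (-180, 180], IUPAC convention
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi torsions of selected residues
#'
#' Computes the standard IUPAC backbone dihedrals
#' phi = C(i-1)-N(i)-CA(i)-C(i) and psi = N(i)-CA(i)-C(i)-N(i+1).
#' Chain termini (and residues with missing backbone atoms) yield `NA`
#' torsions with `defined = FALSE` rather than being dropped, so downstream
#' per-residue tables keep their full length.
#'
#' @param frame A [conformation_frame()].
#' @param selection A [residue_selection()]; defaults to every residue of
#'   the first chain.
#' @return data.frame with columns `residue_index`, `phi`, `psi` (degrees)
#'   and `defined` (logical).
#' @export
compute_torsions <- function(frame, selection = NULL) {
  if (is.null(selection)) {
    ch <- frame$chain_id[1]
    selection <- residue_selection(ch, unique(
      frame$residue_index[frame$chain_id == ch]))
  }
  sub <- frame[frame$chain_id == selection$chain_id, , drop = FALSE]
  atom_of <- function(resid, name) {
    row <- sub[sub$residue_index == resid & sub$atom_name == name, ,
               drop = FALSE]
    if (nrow(row) == 0) return(NULL)
    c(row$x[1], row$y[1], row$z[1])
  }
  res <- selection$residue_indices
  out <- data.frame(residue_index = res, phi = NA_real_, psi = NA_real_,
                    defined = FALSE)
  chain_res <- sort(unique(sub$residue_index))
  for (k in seq_along(res)) {
    i <- res[k]
    prev <- if ((i - 1) %in% chain_res) i - 1 else NA
    nxt <- if ((i + 1) %in% chain_res) i + 1 else NA
    N <- atom_of(i, "N"); CA <- atom_of(i, "CA"); C <- atom_of(i, "C")
    Cprev <- if (!is.na(prev)) atom_of(prev, "C") else NULL
    Nnext <- if (!is.na(nxt)) atom_of(nxt, "N") else NULL
    if (is.null(N) || is.null(CA) || is.null(C) ||
        is.null(Cprev) || is.null(Nnext)) next
    out$phi[k] <- .dihedral(Cprev, N, CA, C)
    out$psi[k] <- .dihedral(N, CA, C, Nnext)
    out$defined[k] <- TRUE
  }
  out
}

#' Per-residue helicity from backbone torsions
#'
#' The helicity of a residue with torsions (phi, psi) is
#' `hp = (1 + cos(phi - phi_alpha)) * (1 + cos(psi - psi_alpha)) / 4`,
#' a smooth score in \[0, 1\] that equals 1 exactly at the reference
#' alpha-helical torsions and decays to 0 when both torsions are 180 deg
#' away. Undefined torsions (termini, missing atoms) give `NA`.
#'
#' @param phi,psi Torsions in degrees (vectors or a data.frame from
#'   [compute_torsions()] passed as `phi`).
#' @param phi_alpha,psi_alpha Reference torsions of a perfect alpha-helix,
#'   degrees. Defaults -57 / -47.
#' @return Numeric vector of helicity values in \[0, 1\] (NA where
#'   undefined).
#' @export
helicity <- function(phi, psi = NULL, phi_alpha = -57, psi_alpha = -47) {
  if (is.data.frame(phi)) {
    tor <- phi
    phi <- ifelse(tor$defined, tor$phi, NA_real_)
    psi <- ifelse(tor$defined, tor$psi, NA_real_)
  }
  d2r <- pi / 180
  (1 + cos((phi - phi_alpha) * d2r)) * (1 + cos((psi - psi_alpha) * d2r)) / 4
}

#' Principal axis of a residue selection
#'
#' Dominant eigenvector of the covariance of the selected Calpha
#' coordinates, with sign chosen so that the axis points toward the
#' positive membrane normal. Used both for whole-domain axes and for short
#' sub-helix axes (>= 4 residues recommended).
#'
#' @param frame A [conformation_frame()].
#' @param selection A [residue_selection()].
#' @param normal Reference direction fixing the sign, default +z.
#' @param atom_name Atom used for the axis fit, default `"CA"`.
#' @return Unit 3-vector.
#' @export
principal_axis <- function(frame, selection, normal = c(0, 0, 1),
                           atom_name = "CA") {
  sub <- select_atoms(frame, selection, atom_name = atom_name)
  xyz <- coords(sub)
  if (nrow(xyz) < 3) stop("need >= 3 atoms for a principal axis")
  cv <- stats::cov(xyz)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1] < 1e-10)
    stop("degenerate point cloud: zero spatial extent")
  # an axis is meaningless when the two leading eigenvalues tie (isotropic
  # or planar-symmetric cloud)
  if ((eg$values[1] - eg$values[2]) / eg$values[1] < 1e-8)
    stop("degenerate point cloud: no dominant principal axis")
  ax <- eg$vectors[, 1]
  if (sum(ax * normal) < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

#' Bend angle of a sub-helix against a reference axis
#'
#' Angle in degrees between the principal axis of a sub-helix selection and
#' a reference axis (typically the principal axis of the whole
#' voltage-sensing domain). This is the metric behind the ~80 degree S4
#' bend of the activated hyperpolarization-gated sensor.
#'
#' @param frame A [conformation_frame()].
#' @param sub_helix A [residue_selection()] with >= 4 residues.
#' @param reference_axis Unit 3-vector.
#' @return Angle in degrees in \[0, 180\].
#' @export
bend_angle <- function(frame, sub_helix, reference_axis) {
  if (length(sub_helix$residue_indices) < 4)
    stop("sub-helix needs >= 4 residues")
  ax <- principal_axis(frame, sub_helix, normal = reference_axis)
  ct <- sum(ax * reference_axis) /
    sqrt(sum(ax^2) * sum(reference_axis^2))
  acos(pmin(pmax(ct, -1), 1)) * 180 / pi
}

# Kabsch optimal rotation aligning moving onto fixed (both n x 3, centred,
# applied on the right: moving %*% R)
.kabsch <- function(moving, fixed) {
  H <- t(moving) %*% fixed
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' RMSD of a frame to a reference conformation
#'
#' Root mean square deviation over the selected atoms, optionally after
#' optimal rigid-body (Kabsch) superposition on the same selection. Atoms
#' are matched by (chain, residue, atom name); a mismatch in the matched
#' sets is an error listing the unmatched residues.
#'
#' @param frame,reference [conformation_frame()] objects.
#' @param selection A [residue_selection()].
#' @param superpose Align before measuring (default `TRUE`).
#' @param atom_name Restrict to one atom name, or `NULL` for all atoms of
#'   the selected residues.
#' @return RMSD in Angstrom.
#' @export
rmsd_to_reference <- function(frame, reference, selection,
                              superpose = TRUE, atom_name = "CA") {
  a <- select_atoms(frame, selection, atom_name = atom_name)
  b <- select_atoms(reference, selection, atom_name = atom_name)
  key <- function(df) paste(df$chain_id, df$residue_index, df$atom_name)
  ka <- key(a); kb <- key(b)
  if (!setequal(ka, kb) || anyDuplicated(ka) || anyDuplicated(kb)) {
    bad <- union(setdiff(ka, kb), setdiff(kb, ka))
    stop("atom correspondence mismatch: ",
         paste(utils::head(bad, 10), collapse = "; "))
  }
  b <- b[match(ka, kb), , drop = FALSE]
  xa <- coords(a); xb <- coords(b)
  if (superpose) {
    ca <- colMeans(xa); cb <- colMeans(xb)
    xa <- sweep(xa, 2, ca); xb <- sweep(xb, 2, cb)
    R <- .kabsch(xa, xb)
    xa <- xa %*% R
  }
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' Contact persistence between two residue groups across frames
#'
#' A residue pair is "in contact" in a frame when any heavy-atom pair
#' distance is at or below `cutoff`; persistence is the fraction of frames
#' in contact. Used for the voltage-sensor/pore interaction network, where
#' contacts maintained throughout the trajectory define the coupling
#' pathways.
#'
#' @param frames List of [conformation_frame()] objects.
#' @param groupA,groupB [residue_selection()] objects.
#' @param cutoff Heavy-atom distance cutoff, Angstrom (default 4.5).
#' @param keep_zero Keep never-contacting pairs with persistence 0
#'   (default `FALSE`: such pairs are absent from the table).
#' @return data.frame with columns `chain_a`, `resid_a`, `chain_b`,
#'   `resid_b`, `persistence`.
#' @export
contact_persistence <- function(frames, groupA, groupB, cutoff = 4.5,
                                keep_zero = FALSE) {
  if (length(frames) == 0) stop("no frames supplied")
  if (cutoff <= 0) stop("cutoff must be positive")
  pairs <- expand.grid(resid_a = groupA$residue_indices,
                       resid_b = groupB$residue_indices)
  # drop self-pairs and unordered duplicates when the groups share a chain
  if (identical(groupA$chain_id, groupB$chain_id)) {
    pairs <- pairs[pairs$resid_a < pairs$resid_b, , drop = FALSE]
  }
  if (nrow(pairs) == 0) stop("no residue pairs to evaluate")
  hits <- matrix(0, nrow(pairs), 1)
  for (fr in frames) {
    a <- select_atoms(fr, groupA)
    b <- select_atoms(fr, groupB)
    a <- a[a$element != "H", , drop = FALSE]
    b <- b[b$element != "H", , drop = FALSE]
    for (p in seq_len(nrow(pairs))) {
      xa <- coords(a[a$residue_index == pairs$resid_a[p], , drop = FALSE])
      xb <- coords(b[b$residue_index == pairs$resid_b[p], , drop = FALSE])
      d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
      if (min(d2) <= cutoff^2 + 1e-12) hits[p] <- hits[p] + 1
    }
  }
  out <- data.frame(chain_a = groupA$chain_id, resid_a = pairs$resid_a,
                    chain_b = groupB$chain_id, resid_b = pairs$resid_b,
                    persistence = as.numeric(hits) / length(frames))
  if (!keep_zero) out <- out[out$persistence > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
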