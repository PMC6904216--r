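# Shrake-Rupley solvent accessible surface area and state-dependent
# accessibility calls. The probe radius default is 2.9 A, the approximate
# radius of the MTSET reagent used in substituted-cysteine accessibility,
# so that "accessible" means reachable by the probe rather than by water.

#' Deterministic quasi-uniform sphere points (golden spiral)
#'
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)               # polar angle
  theta <- pi * (1 + sqrt(5)) * i          # golden-angle azimuth
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Classic test-point SASA: each atom is expanded to radius
#' `vdw_radius + probe_radius`, covered with `n_points` deterministic
#' golden-spiral points, and a point is accessible when it lies outside
#' every neighbouring expanded sphere. The per-atom area is the accessible
#' point fraction times the expanded-sphere area; per-residue areas are
#' exact sums of their atoms. No randomness is involved, so results are
#' bit-stable across runs.
#'
#' @param frame A [conformation_frame()].
#' @param probe_radius Probe radius in Angstrom (default 2.9, MTSET-sized).
#' @param n_points Test points per atom (default 960; >= 24 required).
#' @param occluders Optional second [conformation_frame()] whose atoms
#'   occlude but are not reported (e.g. a membrane slab).
#' @return Object of class `sasa_result`: list with `atom_area` (A^2 per
#'   atom), `residue_area` (data.frame `chain_id`, `residue_index`,
#'   `residue_name`, `area`), `probe_radius`, `n_points`.
#' @export
shrake_rupley <- function(frame, probe_radius = 2.9, n_points = 960,
                          occluders = NULL) {
  if (nrow(frame) == 0) stop("frame has zero atoms")
  if (probe_radius <= 0) stop("probe_radius must be positive")
  if (n_points < 24) stop("n_points must be >= 24")
  sph <- golden_spiral_points(n_points)
  xyz <- coords(frame)
  rad <- frame$vdw_radius + probe_radius
  if (!is.null(occluders)) {
    oxyz <- rbind(xyz, coords(occluders))
    orad <- c(rad, occluders$vdw_radius + probe_radius)
  } else {
    oxyz <- xyz; orad <- rad
  }
  n <- nrow(xyz)
  area <- numeric(n)
  # neighbour prefilter: only spheres that can intersect atom i's surface
  for (i in seq_len(n)) {
    pts <- sph * rad[i] +
      matrix(xyz[i, ], nrow = n_points, ncol = 3, byrow = TRUE)
    dc <- sqrt(rowSums(sweep(oxyz, 2, xyz[i, ])^2))
    nb <- which(dc < rad[i] + orad & dc > 1e-9)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- rowSums(sweep(pts, 2, oxyz[j, ])^2)
      exposed <- exposed & d2 > orad[j]^2
      if (!any(exposed)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(exposed) / n_points
  }
  res <- stats::aggregate(
    area, by = list(chain_id = frame$chain_id,
                    residue_index = frame$residue_index), FUN = sum)
  names(res)[3] <- "area"
  key <- paste(frame$chain_id, frame$residue_index)
  rn <- frame$residue_name[!duplicated(key)]
  names(rn) <- key[!duplicated(key)]
  res$residue_name <- rn[paste(res$chain_id, res$residue_index)]
  res <- res[order(res$chain_id, res$residue_index),
             c("chain_id", "residue_index", "residue_name", "area")]
  rownames(res) <- NULL
  structure(list(atom_area = area, residue_area = res,
                 probe_radius = probe_radius, n_points = n_points),
            class = "sasa_result")
}

#' State-dependent accessibility calls
#'
#' Computes per-residue SASA in an "up" (resting) and a "down" (activated)
#' conformation at the probe radius, thresholds each state, and classifies
#' the change as `gain` (buried up, exposed down), `loss`, or `unchanged`.
#' This mirrors the prediction of which substituted cysteines a polar
#' reagent applied from solution can modify in a state-dependent fashion.
#'
#' @param up,down [conformation_frame()] objects of the two states.
#' @param selection A [residue_selection()] of positions to call.
#' @param probe_radius Probe radius (default 2.9 A).
#' @param threshold Area cut for "accessible", A^2 (default 5).
#' @param n_points Test points per atom (default 960).
#' @param occluders_up,occluders_down Optional occluder frames per state.
#' @return data.frame with columns `chain_id`, `residue_index`,
#'   `residue_name`, `sasa_up`, `sasa_down`, `accessible_up`,
#'   `accessible_down`, `delta_class`, plus attribute `threshold`.
#' @export
state_accessibility <- function(up, down, selection, probe_radius = 2.9,
                                threshold = 5, n_points = 960,
                                occluders_up = NULL, occluders_down = NULL) {
  su <- shrake_rupley(select_atoms(up, selection), probe_radius, n_points,
                      occluders = if (is.null(occluders_up)) up else
                        rbind_frames(up, occluders_up))
  sd_ <- shrake_rupley(select_atoms(down, selection), probe_radius, n_points,
                       occluders = if (is.null(occluders_down)) down else
                         rbind_frames(down, occluders_down))
  a <- su$residue_area; b <- sd_$residue_area
  m <- match(paste(a$chain_id, a$residue_index),
             paste(b$chain_id, b$residue_index))
  out <- data.frame(
    chain_id = a$chain_id, residue_index = a$residue_index,
    residue_name = a$residue_name,
    sasa_up = a$area, sasa_down = b$area[m])
  out$accessible_up <- out$sasa_up >= threshold
  out$accessible_down <- out$sasa_down >= threshold
  out$delta_class <- ifelse(
    out$accessible_down & !out$accessible_up, "gain",
    ifelse(out$accessible_up & !out$accessible_down, "loss", "unchanged"))
  attr(out, "threshold") <- threshold
  out
}

# concatenate two frames as occluder sets (metadata of the first kept)
rbind_frames <- function(a, b) {
  df <- rbind(as.data.frame(a), as.data.frame(b))
  attr(df, "state_label") <- attr(a, "state_label")
  class(df) <- c("conformation_frame", "data.frame")
  df
}
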