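# Coupling-function decomposition of the gating charge.
#
# The fraction f(r) of the applied transmembrane voltage felt at a point r
# is estimated as the rate of change of the local electrostatic potential
# with the applied voltage, f = d(phi)/d(Vm), from potential maps computed
# under two or more voltages. The gating-charge contribution of residue j
# is then
#     Qj = sum_i q_ij * [ f_a(r_ij) - f_r(r_ij) ],
# the sum running over the partial charges q_ij of that residue, with the
# coupling function of the activated state evaluated at the activated-state
# atom positions and that of the resting state at the resting-state
# positions. The net gating charge per sensor is Q = sum_j Qj.

#' Coupling function at atom positions
#'
#' Interpolates each potential grid at the atom positions of a frame and
#' estimates `f = d(phi)/d(Vm)` per atom. With exactly two grids this is
#' the finite difference `(phi(Vm1) - phi(Vm2)) / (Vm1 - Vm2)`; with more
#' it is the least-squares slope of phi against Vm, which is how maps from
#' several simulated holding potentials are combined.
#'
#' @param frame A [conformation_frame()].
#' @param grids List of [potential_grid()] objects at distinct applied
#'   voltages.
#' @return Object of class `coupling_profile`: list with per-atom `f`
#'   (dimensionless), `atom_id`, `residue_index`, `chain_id`,
#'   `state_label`, `voltages` (mV).
#' @export
coupling_function <- function(frame, grids) {
  if (length(grids) < 2) stop("need >= 2 potential grids")
  volts <- vapply(grids, function(g) g$applied_voltage, numeric(1))
  if (any(duplicated(volts)))
    stop("applied voltages must be distinct; got ",
         paste(volts, collapse = ", "), " mV")
  pts <- coords(frame)
  phi <- vapply(grids, function(g) interpolate_potential(g, pts),
                numeric(nrow(pts)))
  phi <- matrix(phi, nrow = nrow(pts))
  if (length(grids) == 2) {
    f <- (phi[, 1] - phi[, 2]) / (volts[1] - volts[2])
  } else {
    # slope of phi vs Vm per atom, closed-form least squares
    # (centred design, so the intercept drops out of the slope)
    vc <- volts - mean(volts)
    f <- as.numeric(phi %*% vc) / sum(vc^2)
  }
  structure(list(f = f, atom_id = frame$atom_id,
                 residue_index = frame$residue_index,
                 chain_id = frame$chain_id,
                 state_label = attr(frame, "state_label"),
                 voltages = volts),
            class = "coupling_profile")
}

#' Per-residue gating charge between two states
#'
#' Decomposes the gating charge into residue contributions
#' `Qj = sum_i q_ij * (f_a(r_ij) - f_r(r_ij))`. By default the coupling
#' function of each state is evaluated at that state's own atom positions
#' (a moving charge in a static field then contributes through its
#' displacement, and a static charge in a rearranging field through the
#' change of f at its position). Set `shared_positions = "resting"` or
#' `"activated"` to evaluate both states at one set of coordinates for
#' sensitivity analysis.
#'
#' @param frame_r,frame_a Resting and activated [conformation_frame()]s
#'   with identical residue topology.
#' @param profile_r,profile_a Matching `coupling_profile` objects from
#'   [coupling_function()].
#' @param charges Named numeric vector of partial charges (e0) indexed by
#'   atom id, or a data.frame with columns `atom_id`, `charge`.
#' @param shared_positions `"none"` (default), `"resting"` or
#'   `"activated"`.
#' @return Object of class `gating_charge_table`: data.frame with columns
#'   `chain_id`, `residue_index`, `residue_name`, `Q` (e0), plus attributes
#'   `net_per_vsd` and `cumulative`.
#' @export
per_residue_charge <- function(frame_r, frame_a, profile_r, profile_a,
                               charges, shared_positions = "none") {
  key_r <- paste(frame_r$chain_id, frame_r$residue_index)
  key_a <- paste(frame_a$chain_id, frame_a$residue_index)
  if (!identical(sort(unique(key_r)), sort(unique(key_a))))
    stop("residue topology differs between states")
  if (is.data.frame(charges)) {
    q <- charges$charge
    names(q) <- as.character(charges$atom_id)
    charges <- q
  }
  qr <- charges[as.character(frame_r$atom_id)]
  qa <- charges[as.character(frame_a$atom_id)]
  if (any(is.na(qr)) || any(is.na(qa)))
    stop("missing partial charge for atom id(s): ",
         paste(utils::head(frame_r$atom_id[is.na(qr)], 5), collapse = ", "))
  if (any(!is.finite(qr))) stop("partial charges must be finite")
  fa <- profile_a$f
  fr <- profile_r$f
  if (shared_positions == "resting") {
    # re-pair activated f values onto resting atom order by atom id
    fa <- fa[match(frame_r$atom_id, profile_a$atom_id)]
  } else if (shared_positions == "activated") {
    fr <- fr[match(frame_a$atom_id, profile_r$atom_id)]
  } else if (shared_positions != "none") {
    stop("shared_positions must be 'none', 'resting' or 'activated'")
  }
  # per-atom contribution q_i * (fa_i - fr_i); atoms matched by id
  m <- match(frame_r$atom_id, frame_a$atom_id)
  if (any(is.na(m))) stop("atom ids differ between states")
  contrib <- qa[m] * fa[m] - qr * fr
  agg <- stats::aggregate(
    contrib,
    by = list(chain_id = frame_r$chain_id,
              residue_index = frame_r$residue_index),
    FUN = sum)
  names(agg)[3] <- "Q"
  rn <- frame_r$residue_name[!duplicated(paste(frame_r$chain_id,
                                               frame_r$residue_index))]
  names(rn) <- key_r[!duplicated(key_r)]
  agg$residue_name <- rn[paste(agg$chain_id, agg$residue_index)]
  agg <- agg[order(agg$chain_id, agg$residue_index),
             c("chain_id", "residue_index", "residue_name", "Q")]
  rownames(agg) <- NULL
  attr(agg, "net_per_vsd") <- sum(agg$Q)
  attr(agg, "cumulative") <- cumsum(agg$Q)
  class(agg) <- c("gating_charge_table", "data.frame")
  agg
}

#' Aggregate gating-charge tables over conformations
#'
#' Averages the per-residue contributions over independently extracted
#' conformations of each state, reporting the mean `Q` per residue, its
#' standard error across conformations, the cumulative charge in sequence
#' order, the mean net charge per sensor and the per-channel total
#' (`subunits * net`, assuming identical independent sensors).
#'
#' @param tables List of `gating_charge_table` objects over matching
#'   residue sets.
#' @param subunits Number of voltage sensors per channel (default 4).
#' @return List with `per_residue` (data.frame: `chain_id`,
#'   `residue_index`, `residue_name`, `mean_Q`, `stderr`, `cumulative`,
#'   `cumulative_stderr`), `net_per_vsd`, `net_stderr`, `per_channel`,
#'   `n_conformations`.
#' @export
aggregate_charge <- function(tables, subunits = 4) {
  if (length(tables) < 1) stop("need >= 1 table")
  if (subunits < 1) stop("subunits must be >= 1")
  keys <- lapply(tables, function(t) paste(t$chain_id, t$residue_index))
  for (k in keys[-1]) if (!identical(k, keys[[1]]))
    stop("inconsistent residue sets across tables")
  Q <- vapply(tables, function(t) t$Q, numeric(nrow(tables[[1]])))
  Q <- matrix(Q, nrow = nrow(tables[[1]]))
  n <- length(tables)
  mean_Q <- rowMeans(Q)
  stderr <- if (n > 1) apply(Q, 1, stats::sd) / sqrt(n) else
    rep(NA_real_, nrow(Q))
  cum <- apply(Q, 2, cumsum)
  cum <- matrix(cum, nrow = nrow(Q))
  cum_mean <- rowMeans(cum)
  cum_se <- if (n > 1) apply(cum, 1, stats::sd) / sqrt(n) else
    rep(NA_real_, nrow(Q))
  nets <- colSums(Q)
  per_residue <- data.frame(
    chain_id = tables[[1]]$chain_id,
    residue_index = tables[[1]]$residue_index,
    residue_name = tables[[1]]$residue_name,
    mean_Q = mean_Q, stderr = stderr,
    cumulative = cum_mean, cumulative_stderr = cum_se)
  list(per_residue = per_residue,
       net_per_vsd = mean(nets),
       net_stderr = if (n > 1) stats::sd(nets) / sqrt(n) else NA_real_,
       per_channel = subunits * mean(nets),
       n_conformations = n)
}
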