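# Water-count profiles along the membrane normal, summarised as percentile
# bands across frames (the hydration "envelope" of the voltage-sensor
# crevices).

#' Hydration profile along the membrane normal
#'
#' Counts water oxygens per bin along the membrane normal, inside an
#' optional counting region, for every frame; then summarises each bin by
#' the 10/25/50/75/90 percentiles across frames. The default region is a
#' cylinder about a stated axis point, since the physically relevant waters
#' are those in the sensor's crevices rather than bulk.
#'
#' @param frames List of [conformation_frame()] objects.
#' @param water_selection A [residue_selection()] matching water residues,
#'   or `NULL` to use all atoms named `"OH2"` or `"OW"` or residues named
#'   `"HOH"`/`"TIP3"`/`"SOL"`/`"WAT"`.
#' @param mframe A [membrane_frame()].
#' @param bin_width Bin width along the normal, Angstrom (default 3).
#' @param region Either `NULL` (no lateral restriction), a list
#'   `list(kind = "cylinder", center = c(x, y), radius = r)`, or
#'   `list(kind = "box", xlim = , ylim = )`; z-extent always comes from
#'   `zlim`.
#' @param zlim Profile range along the normal relative to `reference_z`
#'   (default the membrane slab bounds widened by 10 A each side).
#' @return Object of class `hydration_profile`: list with `bin_edges`,
#'   `counts` (frames x bins matrix) and `percentiles` (5 x bins matrix,
#'   rows p10/p25/p50/p75/p90).
#' @export
hydration_profile <- function(frames, water_selection = NULL, mframe,
                              bin_width = 3, region = NULL, zlim = NULL) {
  if (length(frames) == 0) stop("no frames supplied")
  if (bin_width <= 0) stop("bin_width must be positive")
  if (is.null(zlim))
    zlim <- mframe$slab_bounds + c(-10, 10)
  edges <- seq(zlim[1], zlim[2], by = bin_width)
  if (utils::tail(edges, 1) < zlim[2]) edges <- c(edges, zlim[2])
  nb <- length(edges) - 1
  counts <- matrix(0L, nrow = length(frames), ncol = nb)
  water_names <- c("HOH", "TIP3", "SOL", "WAT")
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    if (!is.null(water_selection)) {
      w <- select_atoms(fr, water_selection)
      w <- w[w$element == "O", , drop = FALSE]
    } else {
      w <- fr[fr$residue_name %in% water_names &
                fr$atom_name %in% c("OH2", "OW", "O"), , drop = FALSE]
    }
    if (nrow(w) == 0) next
    keep <- rep(TRUE, nrow(w))
    if (!is.null(region)) {
      if (identical(region$kind, "cylinder")) {
        keep <- (w$x - region$center[1])^2 + (w$y - region$center[2])^2 <=
          region$radius^2
      } else if (identical(region$kind, "box")) {
        keep <- w$x >= region$xlim[1] & w$x <= region$xlim[2] &
          w$y >= region$ylim[1] & w$y <= region$ylim[2]
      } else stop("unknown region kind: ", region$kind)
    }
    w <- w[keep, , drop = FALSE]
    zproj <- as.numeric(coords(w) %*% mframe$normal) - mframe$reference_z
    h <- graphics::hist(zproj[zproj >= zlim[1] & zproj <= zlim[2]],
                        breaks = edges, plot = FALSE)
    counts[fi, ] <- h$counts
  }
  pct <- apply(counts, 2, stats::quantile,
               probs = c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7)
  rownames(pct) <- c("p10", "p25", "p50", "p75", "p90")
  structure(list(bin_edges = edges, counts = counts, percentiles = pct),
            class = "hydration_profile")
}
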