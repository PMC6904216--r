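# Core domain containers: conformation frames, membrane frames, selections.
# A conformation frame is a plain data.frame of atoms plus a class attribute,
# one row per atom, in a membrane-aligned coordinate frame (z = normal by
# convention throughout the package).

# Bondi (1964) van der Waals radii, in Angstrom. The radius of an element
# absent from this table falls back to .vdw_default.
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, "NA" = 2.27, K = 2.75,
  MG = 1.73, CA = 2.31, ZN = 1.39, FE = 2.00, SE = 1.90
)
.vdw_default <- 1.70

#' Van der Waals radius lookup
#'
#' Returns the Bondi van der Waals radius for each element symbol. Elements
#' not in the bundled table receive the documented default of 1.70 Angstrom
#' (the carbon radius), which is the common fallback for heavy atoms.
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- .vdw_default
  unname(r)
}

#' Construct a conformation frame
#'
#' A conformation frame holds the atoms of one structural snapshot (one model
#' of a multi-model PDB, or one synthetic fixture) with residue and chain
#' metadata, in a membrane-aligned coordinate frame. It is the common
#' currency of all geometric and electrostatic analyses in the package.
#'
#' @param atom_id Integer atom serial numbers.
#' @param x,y,z Coordinates in Angstrom.
#' @param element Element symbols.
#' @param residue_index Integer residue number per atom.
#' @param residue_name Three-letter residue code per atom.
#' @param chain_id Chain identifier per atom.
#' @param atom_name PDB atom-name string per atom (e.g. "CA").
#' @param vdw_radius Van der Waals radius per atom in Angstrom; defaults to
#'   the bundled Bondi table looked up by element.
#' @param state_label Free-form tag for the conformational state, e.g.
#'   "resting" or "activated".
#' @return An object of class `conformation_frame` (a data.frame with one
#'   row per atom and attribute `state_label`).
#' @export
conformation_frame <- function(atom_id, x, y, z, element, residue_index,
                               residue_name, chain_id = "A",
                               atom_name = element,
                               vdw_radius = NULL,
                               state_label = "unspecified") {
  n <- max(length(atom_id), length(x), length(y), length(z),
           length(residue_index))
  ok_len <- function(v) length(v) %in% c(1L, n)
  stopifnot(ok_len(x), ok_len(y), ok_len(z), ok_len(atom_id),
            ok_len(residue_index))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  atom_id <- rep_len(atom_id, n)
  residue_index <- rep_len(residue_index, n)
  element <- rep_len(element, n)
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("coordinates must be finite")
  if (is.null(vdw_radius)) vdw_radius <- vdw_radius_of(element)
  vdw_radius <- rep_len(vdw_radius, n)
  if (any(vdw_radius <= 0)) stop("vdw_radius must be positive")
  df <- data.frame(
    atom_id = as.integer(atom_id),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    element = as.character(element),
    vdw_radius = as.numeric(vdw_radius),
    residue_index = as.integer(residue_index),
    residue_name = as.character(rep_len(residue_name, n)),
    chain_id = as.character(rep_len(chain_id, n)),
    atom_name = as.character(rep_len(atom_name, n)),
    stringsAsFactors = FALSE
  )
  # residue indices must be non-decreasing within a chain so that sequence
  # order (cumulative charge curves, torsion neighbours) is well defined
  for (ch in unique(df$chain_id)) {
    ri <- df$residue_index[df$chain_id == ch]
    if (is.unsorted(unique(ri)) && is.unsorted(rev(unique(ri))))
      stop("residue indices must be ordered within chain ", ch)
  }
  attr(df, "state_label") <- state_label
  class(df) <- c("conformation_frame", "data.frame")
  df
}

# internal alias so conformation_frame() can default its argument from the
# exported lookup without name collision
vdw_radius_of <- function(element) vdw_radius(element)

#' @export
print.conformation_frame <- function(x, ...) {
  cat("conformation_frame:", nrow(x), "atoms,",
      length(unique(paste(x$chain_id, x$residue_index))), "residues,",
      "state =", attr(x, "state_label"), "\n")
  invisible(x)
}

#' Coordinates of a frame as a matrix
#' @param frame A `conformation_frame`.
#' @return n x 3 numeric matrix of coordinates in Angstrom.
#' @export
coords <- function(frame) {
  as.matrix(frame[, c("x", "y", "z")])
}

#' Construct a membrane coordinate frame
#'
#' Defines the membrane normal, the z-projection of a named reference atom
#' (by convention the Calpha of the charge-transfer-center phenylalanine),
#' and the slab bounds of the hydrophobic core along the normal.
#'
#' @param normal Unit 3-vector giving the membrane normal (default +z).
#' @param reference_z Projection of the reference atom onto the normal, in
#'   Angstrom. Displacements are reported relative to this value.
#' @param slab_bounds Length-2 numeric, inner/outer membrane boundary along
#'   the normal in Angstrom.
#' @return An object of class `membrane_frame`.
#' @export
membrane_frame <- function(normal = c(0, 0, 1), reference_z = 0,
                           slab_bounds = c(-15, 15)) {
  normal <- as.numeric(normal)
  stopifnot(length(normal) == 3, length(slab_bounds) == 2)
  nrm <- sqrt(sum(normal^2))
  if (abs(nrm - 1) > 1e-9) {
    if (nrm == 0) stop("normal must be a non-zero vector")
    normal <- normal / nrm
  }
  if (!(slab_bounds[1] < slab_bounds[2]))
    stop("slab_bounds must be increasing")
  structure(list(normal = normal, reference_z = as.numeric(reference_z),
                 slab_bounds = as.numeric(slab_bounds)),
            class = "membrane_frame")
}

#' Construct a residue selection
#'
#' @param chain_id Chain label.
#' @param residue_indices Integer vector of residue numbers.
#' @param role Free-form tag, e.g. "S4", "gating_charges".
#' @return An object of class `residue_selection`.
#' @export
residue_selection <- function(chain_id = "A", residue_indices, role = "") {
  residue_indices <- as.integer(residue_indices)
  if (length(residue_indices) == 0) stop("selection must be non-empty")
  structure(list(chain_id = as.character(chain_id),
                 residue_indices = unique(residue_indices),
                 role = role),
            class = "residue_selection")
}

# Rows of `frame` matching a selection; errors if a requested residue is
# absent so silent misuse of residue numbering cannot pass unnoticed.
select_atoms <- function(frame, selection, atom_name = NULL) {
  keep <- frame$chain_id == selection$chain_id &
    frame$residue_index %in% selection$residue_indices
  if (!is.null(atom_name)) keep <- keep & frame$atom_name == atom_name
  present <- unique(frame$residue_index[keep])
  missing <- setdiff(selection$residue_indices, present)
  if (length(missing) > 0)
    stop("selection does not resolve in frame; missing residue(s) ",
         paste(missing, collapse = ", "),
         if (!is.null(atom_name)) paste0(" (atom ", atom_name, ")"))
  frame[keep, , drop = FALSE]
}

#' Project selected atoms onto the membrane normal
#'
#' Computes, for one named atom in each selected residue, the displacement
#' along the membrane normal relative to the reference z of the membrane
#' frame: `r . normal - reference_z`. This is the quantity plotted as
#' "displacement of the gating charges along the membrane normal measured
#' relative to the charge transfer center".
#'
#' @param frame A `conformation_frame`.
#' @param selection A `residue_selection`.
#' @param mframe A `membrane_frame`.
#' @param atom_name Atom to project, default `"CA"`.
#' @return Named numeric vector of displacements in Angstrom, one per
#'   selected residue (names are residue indices).
#' @export
project_onto_normal <- function(frame, selection, mframe, atom_name = "CA") {
  sub <- select_atoms(frame, selection, atom_name = atom_name)
  # one atom per residue expected; keep first if alternates present
  sub <- sub[!duplicated(sub$residue_index), , drop = FALSE]
  missing <- setdiff(selection$residue_indices, sub$residue_index)
  if (length(missing) > 0)
    stop("atom ", atom_name, " missing in residue(s) ",
         paste(missing, collapse = ", "))
  sub <- sub[order(match(sub$residue_index, selection$residue_indices)), ]
  proj <- as.numeric(coords(sub) %*% mframe$normal) - mframe$reference_z
  names(proj) <- sub$residue_index
  proj
}
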