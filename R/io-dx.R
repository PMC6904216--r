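# OpenDX scalar-grid I/O and trilinear interpolation. Electrostatic
# potential maps enter the package as pre-computed grids tagged with the
# transmembrane voltage under which they were obtained; the package never
# solves for the potential itself.

#' Construct a potential grid
#'
#' A 3D scalar field of electrostatic potential on a regular grid, tagged
#' with the applied transmembrane voltage `Vm` under which it was computed.
#' Grid values and voltages are in millivolt; origin/spacing in Angstrom.
#' Values are node-registered: `values[i,j,k]` sits at
#' `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @param origin Length-3 numeric, position of the first grid node (A).
#' @param spacing Length-3 numeric, grid step along x, y, z (A).
#' @param values 3D numeric array of potentials (mV).
#' @param applied_voltage Transmembrane voltage Vm of this map (mV).
#' @return An object of class `potential_grid`.
#' @export
potential_grid <- function(origin, spacing, values, applied_voltage) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  stopifnot(length(origin) == 3, length(spacing) == 3)
  if (any(spacing <= 0)) stop("spacing must be positive on all axes")
  if (length(dim(values)) != 3 || any(dim(values) < 2))
    stop("values must be a 3D array with >= 2 nodes per axis")
  if (any(!is.finite(values))) stop("grid contains non-finite values")
  structure(list(origin = origin, spacing = spacing,
                 values = values,
                 applied_voltage = as.numeric(applied_voltage)),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat("potential_grid:", paste(dim(x$values), collapse = "x"),
      "nodes, Vm =", x$applied_voltage, "mV\n")
  invisible(x)
}

#' Read an OpenDX scalar grid
#'
#' Parses the "regular positions, regular connections" OpenDX format used
#' by electrostatics tools (APBS, VMD plugins). The applied transmembrane
#' voltage is not part of the DX format and must be supplied by the caller.
#'
#' @param path Path to a `.dx` file.
#' @param applied_voltage Vm in mV to attach as metadata.
#' @return A [potential_grid()].
#' @export
read_potential_grid <- function(path, applied_voltage) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  cnt <- grep("object 1 class gridpositions counts", lines, value = TRUE)
  org <- grep("^origin", lines, value = TRUE)
  dlt <- grep("^delta", lines, value = TRUE)
  if (length(cnt) != 1 || length(org) != 1 || length(dlt) != 3)
    stop("malformed DX header in ", path)
  nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  counts <- as.integer(nums(sub(".*counts", "", cnt)))
  origin <- nums(sub("origin", "", org))
  deltas <- t(vapply(dlt, function(l) nums(sub("delta", "", l)),
                     numeric(3)))
  # require axis-aligned deltas (diagonal delta matrix)
  if (any(abs(deltas[upper.tri(deltas) | lower.tri(deltas)]) > 1e-12))
    stop("only axis-aligned DX grids are supported")
  spacing <- diag(deltas)
  data_start <- grep("object 3 class array", lines)
  if (length(data_start) != 1) stop("malformed DX header in ", path)
  tail_lines <- lines[(data_start + 1):length(lines)]
  tail_lines <- tail_lines[!grepl("^(attribute|component|object|end)", tail_lines)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(
    tail_lines[nzchar(trimws(tail_lines))]), "\\s+"))))
  n <- prod(counts)
  if (length(vals) != n || any(is.na(vals)))
    stop("DX data block malformed or contains non-numeric values in ", path)
  if (any(!is.finite(vals))) stop("DX grid contains non-finite values")
  # DX stores with z fastest; R arrays are x fastest
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  potential_grid(origin, spacing, arr, applied_voltage)
}

#' Write a potential grid in OpenDX scalar format
#'
#' @param grid A [potential_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_potential_grid <- function(grid, path) {
  d <- dim(grid$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# OpenDX scalar grid, Vm = %g mV", grid$applied_voltage),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing[1]),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing[2]),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))
  ), con)
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z fastest
  n3 <- (length(vals) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(vals[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.10g %.10g %.10g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(vals))
    writeLines(paste(sprintf("%.10g", vals[(n3 + 1):length(vals)]),
                     collapse = " "), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Trilinear interpolation of a potential grid
#'
#' Evaluates the scalar field at arbitrary points by trilinear
#' interpolation between the 8 surrounding nodes. Points outside the grid
#' raise an error listing the offending rows, since extrapolated potentials
#' would silently corrupt coupling functions.
#'
#' @param grid A [potential_grid()].
#' @param points n x 3 matrix of coordinates (A).
#' @return Numeric vector of interpolated potentials (mV).
#' @export
interpolate_potential <- function(grid, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  d <- dim(grid$values)
  # fractional node coordinates, 0-based
  t_ <- sweep(sweep(points, 2, grid$origin, "-"), 2, grid$spacing, "/")
  eps <- 1e-9
  out_of_bounds <- t_[, 1] < -eps | t_[, 1] > d[1] - 1 + eps |
    t_[, 2] < -eps | t_[, 2] > d[2] - 1 + eps |
    t_[, 3] < -eps | t_[, 3] > d[3] - 1 + eps
  if (any(out_of_bounds))
    stop("point(s) outside grid bounds: rows ",
         paste(which(out_of_bounds), collapse = ", "))
  t_ <- pmin(pmax(t_, 0), matrix(rep(d - 1, each = nrow(t_)), ncol = 3))
  i0 <- pmin(floor(t_), matrix(rep(d - 2, each = nrow(t_)), ncol = 3))
  f <- t_ - i0
  v <- grid$values
  idx <- function(dx, dy, dz)
    v[cbind(i0[, 1] + 1 + dx, i0[, 2] + 1 + dy, i0[, 3] + 1 + dz)]
  c000 <- idx(0, 0, 0); c100 <- idx(1, 0, 0)
  c010 <- idx(0, 1, 0); c110 <- idx(1, 1, 0)
  c001 <- idx(0, 0, 1); c101 <- idx(1, 0, 1)
  c011 <- idx(0, 1, 1); c111 <- idx(1, 1, 1)
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}
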