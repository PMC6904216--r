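# Multi-model PDB reading/writing. Multi-model PDB is the package's
# trajectory interchange format: MODEL/ENDMDL records delimit frames, so
# snapshots exported from any MD engine can be analysed without binary
# trajectory readers. Fixed-column parsing per the PDB v3.3 ATOM record.

.parse_atom_line <- function(line, lineno) {
  if (nchar(line) < 54)
    stop("unparsable ATOM record at line ", lineno, ": '", line, "'")
  out <- list(
    atom_id = suppressWarnings(as.integer(substr(line, 7, 11))),
    atom_name = trimws(substr(line, 13, 16)),
    residue_name = trimws(substr(line, 18, 20)),
    chain_id = trimws(substr(line, 22, 22)),
    residue_index = suppressWarnings(as.integer(substr(line, 23, 26))),
    x = suppressWarnings(as.numeric(substr(line, 31, 38))),
    y = suppressWarnings(as.numeric(substr(line, 39, 46))),
    z = suppressWarnings(as.numeric(substr(line, 47, 54))),
    element = if (nchar(line) >= 78) trimws(substr(line, 77, 78)) else ""
  )
  if (is.na(out$x) || is.na(out$y) || is.na(out$z) ||
      is.na(out$residue_index))
    stop("unparsable ATOM record at line ", lineno, ": '", line, "'")
  if (out$chain_id == "") out$chain_id <- "A"
  if (out$element == "") {
    # derive element from the atom name as PDB readers conventionally do:
    # first alphabetic character, honouring the column-13 element offset
    nm <- gsub("[^A-Za-z]", "", out$atom_name)
    out$element <- toupper(substr(nm, 1, 1))
  }
  out
}

#' Read one model of a (multi-model) PDB file
#'
#' Multi-model PDB files are treated as trajectories: each MODEL/ENDMDL
#' block is one frame. Files without MODEL records contain a single model.
#' Van der Waals radii are assigned from the bundled Bondi table; unknown
#' elements receive the documented default (see [vdw_radius()]).
#'
#' @param path Path to a PDB file.
#' @param model_index 1-based model number to read.
#' @param state_label Tag stored on the returned frame.
#' @return A [conformation_frame()].
#' @export
read_structure <- function(path, model_index = 1, state_label = "unspecified") {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0) {
    blocks <- list(seq_along(lines))
  } else {
    if (length(ends) != length(starts))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    blocks <- mapply(function(s, e) seq(s, e), starts, ends, SIMPLIFY = FALSE)
  }
  if (model_index < 1 || model_index > length(blocks))
    stop("model not found: index ", model_index, " of ",
         length(blocks), " model(s) in ", path)
  idx <- blocks[[model_index]]
  atom_lines <- idx[grepl("^(ATOM  |HETATM)", lines[idx])]
  if (length(atom_lines) == 0) stop("no ATOM/HETATM records in model")
  recs <- lapply(atom_lines, function(i) .parse_atom_line(lines[i], i))
  g <- function(f) sapply(recs, `[[`, f)
  conformation_frame(
    atom_id = g("atom_id"), x = g("x"), y = g("y"), z = g("z"),
    element = g("element"), residue_index = g("residue_index"),
    residue_name = g("residue_name"), chain_id = g("chain_id"),
    atom_name = g("atom_name"), state_label = state_label
  )
}

#' Read all models of a multi-model PDB file
#'
#' @inheritParams read_structure
#' @return List of [conformation_frame()] objects, one per model.
#' @export
read_trajectory <- function(path, state_label = "unspecified") {
  lines <- readLines(path)
  n <- max(1, length(grep("^MODEL", lines)))
  lapply(seq_len(n), function(i)
    read_structure(path, model_index = i, state_label = state_label))
}

#' Write conformation frames as a (multi-model) PDB file
#'
#' One MODEL/ENDMDL block per frame. Coordinates are written at the PDB's
#' fixed precision of 1e-3 Angstrom, which bounds the read-back error.
#'
#' @param frames A single `conformation_frame` or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frames, path) {
  if (inherits(frames, "conformation_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    fr <- frames[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      fr$atom_id %% 100000,
      ifelse(nchar(fr$atom_name) < 4, paste0(" ", fr$atom_name), fr$atom_name),
      fr$residue_name, fr$chain_id, fr$residue_index,
      fr$x, fr$y, fr$z, 1.00, 0.00, toupper(fr$element)
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
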