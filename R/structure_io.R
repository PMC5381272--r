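# Multi-model PDB input/output and atom selection. Parsing and writing are
# delegated to bio3d; this layer adds the trajectory contract (constant atom
# count and ordering across models, frame spacing in ns) and element
# inference for heavy-atom filtering.

# Infer the element symbol from a PDB atom name when the element column is
# blank. Hydrogens are identified by element, never by name prefix alone.
infer_element <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  nm <- gsub("[0-9']", "", nm)
  vapply(nm, function(x) {
    if (nchar(x) == 0L) return("X")
    two <- substr(x, 1L, 2L)
    if (two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "CA")) {
      # bare "CA" in a protein context is an alpha carbon, not calcium
      if (two == "CA") "C" else two
    } else {
      substr(x, 1L, 1L)
    }
  }, character(1), USE.NAMES = FALSE)
}

# Scan MODEL/ENDMDL blocks for per-model ATOM/HETATM counts so that
# inconsistent models can be reported by name before handing off to bio3d.
scan_model_atom_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    return(list(n_models = 1L, counts = sum(is_atom)))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts)) {
    stop(sprintf("malformed multi-model PDB '%s': %d MODEL but %d ENDMDL records",
                 path, length(model_starts), length(model_ends)), call. = FALSE)
  }
  counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, model_ends)
  list(n_models = length(model_starts), counts = as.integer(counts))
}

#' Read a multi-model PDB file as a structure trajectory
#'
#' Frames are returned in file order; hydrogen atoms are retained (use
#' `heavy_only` in [select_atoms()] to drop them). Atom count and ordering
#' must be identical across models; a mismatch is a hard error naming the
#' offending models.
#'
#' @param path PDB file path.
#' @param dt frame spacing in ns (default 0.2).
#' @return A `structure_trajectory`: list with `atoms` (data.frame: serial,
#'   atom_name, residue_name, chain_id, residue_number, element), `xyz`
#'   (n_frames x 3N matrix, Angstrom, bio3d layout), `dt`, `source_label`.
#' @export
read_multimodel_pdb <- function(path, dt = 0.2) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  scan <- scan_model_atom_counts(path)
  if (length(unique(scan$counts)) > 1L) {
    stop(sprintf(
      "inconsistent atom count across models in '%s': %s",
      path,
      paste(sprintf("model %d has %d atoms", seq_along(scan$counts), scan$counts),
            collapse = ", ")), call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  element <- at$elesy
  blank <- is.na(element) | trimws(element) == ""
  if (any(blank)) element[blank] <- infer_element(at$elety[blank])
  atoms <- data.frame(
    serial = at$eleno,
    atom_name = trimws(at$elety),
    residue_name = trimws(at$resid),
    chain_id = at$chain,
    residue_number = at$resno,
    element = trimws(element),
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (!all(is.finite(xyz))) {
    stop(sprintf("non-finite coordinates in '%s'", path), call. = FALSE)
  }
  structure(list(atoms = atoms, xyz = unclass(xyz), dt = dt,
                 source_label = path),
            class = "structure_trajectory")
}

#' @export
print.structure_trajectory <- function(x, ...) {
  cat(sprintf("structure_trajectory: %d frames x %d atoms (dt = %g ns) [%s]\n",
              nrow(x$xyz), nrow(x$atoms), x$dt, x$source_label))
  invisible(x)
}

#' Number of frames in a structure trajectory
#' @param traj a `structure_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame
#' @param traj a `structure_trajectory`.
#' @param i frame index (1-based).
#' @return N x 3 matrix, Angstrom.
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Write a structure trajectory as a multi-model PDB
#'
#' @param traj a `structure_trajectory`.
#' @param path output path.
#' @export
write_multimodel_pdb <- function(traj, path) {
  at <- traj$atoms
  bio3d::write.pdb(
    file = path,
    xyz = traj$xyz,
    type = rep("ATOM", nrow(at)),
    eleno = at$serial,
    elety = at$atom_name,
    resid = at$residue_name,
    chain = at$chain_id,
    resno = at$residue_number,
    elesy = at$element
  )
  invisible(path)
}

#' Select atoms of a structure trajectory
#'
#' Returns 1-based indices into the atom table, preserving atom order. An
#' empty selection is a legal result; downstream operations decide whether
#' that is an error.
#'
#' @param traj a `structure_trajectory` (the atom table is shared by all
#'   frames).
#' @param chain optional chain identifier(s).
#' @param residue_numbers optional integer set.
#' @param residue_names optional residue-name set.
#' @param atom_names optional atom-name set.
#' @param heavy_only if `TRUE`, drop hydrogen/deuterium (by element).
#' @return integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(traj, chain = NULL, residue_numbers = NULL,
                         residue_names = NULL, atom_names = NULL,
                         heavy_only = FALSE) {
  at <- traj$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain_id %in% chain
  if (!is.null(residue_numbers)) keep <- keep & at$residue_number %in% residue_numbers
  if (!is.null(residue_names)) keep <- keep & at$residue_name %in% residue_names
  if (!is.null(atom_names)) keep <- keep & at$atom_name %in% atom_names
  if (isTRUE(heavy_only)) keep <- keep & !(at$element %in% c("H", "D"))
  which(keep)
}
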