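# Clamshell order parameters and glycan-contact geometry. Coordinates come
# in from structure_io in Angstrom (PDB native); everything reported here is
# in nm, the convention used throughout the analysis.

ANGSTROM_PER_NM <- 10

# marker residues quantifying lobe opening, by subunit profile
#' Marker-residue profiles for the interlobe distance
#'
#' `GluN1` uses C-alpha atoms of residues 507 and 701; `GluN2B` uses 503 and
#' 701.
#' @param subunit `"GluN1"` or `"GluN2B"`.
#' @return list with `res_a`, `res_b`, `atom_name`.
#' @export
subunit_profile <- function(subunit = c("GluN1", "GluN2B")) {
  subunit <- match.arg(subunit)
  switch(subunit,
         GluN1 = list(res_a = 507L, res_b = 701L, atom_name = "CA"),
         GluN2B = list(res_a = 503L, res_b = 701L, atom_name = "CA"))
}

resolve_single_atom <- function(traj, residue, atom_name) {
  idx <- select_atoms(traj, residue_numbers = residue, atom_names = atom_name)
  if (length(idx) != 1L) {
    stop(sprintf(
      "selection for residue %d atom '%s' matched %d atoms (need exactly 1)",
      residue, atom_name, length(idx)), call. = FALSE)
  }
  idx
}

#' Interlobe marker distance d
#'
#' Euclidean distance between two marker atoms (default the C-alpha atoms
#' of residues 507 and 701), per frame, in nm. Larger d means a more open
#' clamshell.
#'
#' @param traj a `structure_trajectory`.
#' @param res_a,res_b marker residue numbers.
#' @param atom_name marker atom name.
#' @return numeric vector, one value (nm) per frame.
#' @export
interlobe_distance <- function(traj, res_a = 507L, res_b = 701L,
                               atom_name = "CA") {
  ia <- resolve_single_atom(traj, res_a, atom_name)
  ib <- resolve_single_atom(traj, res_b, atom_name)
  ca <- traj$xyz[, (3L * ia - 2L):(3L * ia), drop = FALSE]
  cb <- traj$xyz[, (3L * ib - 2L):(3L * ib), drop = FALSE]
  sqrt(rowSums((ca - cb)^2)) / ANGSTROM_PER_NM
}

# minimum pairwise distance between two coordinate blocks of one frame (A)
min_cross_distance <- function(xa, xb) {
  # |a - b|^2 = |a|^2 + |b|^2 - 2 a.b, vectorized over the pair grid
  a2 <- rowSums(xa^2)
  b2 <- rowSums(xb^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(xa, xb)
  sqrt(max(0, min(d2)))
}

#' Minimum glycan-to-opposite-lobe heavy-atom distance d_g-ol
#'
#' Shortest distance between heavy atoms of a glycan selection and heavy
#' atoms of the opposite-lobe residue range (default 710 to 723), per
#' frame, in nm.
#'
#' @param traj a `structure_trajectory`.
#' @param glycan_selection atom indices (e.g. from [select_atoms()]) or a
#'   chain id string for the glycan.
#' @param lobe_residues residue-number range of the opposite lobe.
#' @param lobe_chain optional chain restriction for the lobe side.
#' @return numeric vector, one value (nm) per frame.
#' @export
glycan_lobe_min_distance <- function(traj, glycan_selection = "G",
                                     lobe_residues = 710:723,
                                     lobe_chain = NULL) {
  if (is.character(glycan_selection)) {
    gsel <- select_atoms(traj, chain = glycan_selection, heavy_only = TRUE)
  } else {
    gsel <- intersect(as.integer(glycan_selection),
                      select_atoms(traj, heavy_only = TRUE))
  }
  lsel <- select_atoms(traj, chain = lobe_chain,
                       residue_numbers = lobe_residues, heavy_only = TRUE)
  if (length(gsel) == 0L) {
    stop("glycan selection is empty after heavy-atom filtering", call. = FALSE)
  }
  if (length(lsel) == 0L) {
    stop("opposite-lobe selection is empty after heavy-atom filtering",
         call. = FALSE)
  }
  vapply(seq_len(nrow(traj$xyz)), function(f) {
    co <- frame_coords(traj, f)
    min_cross_distance(co[gsel, , drop = FALSE], co[lsel, , drop = FALSE])
  }, numeric(1)) / ANGSTROM_PER_NM
}

#' Contact fraction and per-residue contact profile
#'
#' A frame is "in contact" when the minimum heavy-atom distance between the
#' two selections is below `cutoff` (nm). The per-residue profile reports,
#' for every residue on side b, the fraction of frames in which any of its
#' heavy atoms lies within `cutoff` of side a, sorted by descending
#' engagement.
#'
#' @param traj a `structure_trajectory`.
#' @param selection_a,selection_b atom index vectors (heavy atoms are
#'   filtered internally).
#' @param cutoff contact cutoff, nm (default 0.5).
#' @return list with `fraction`, `profile` (data.frame residue_number,
#'   fraction), `cutoff`, `n_frames`.
#' @export
contact_fraction <- function(traj, selection_a, selection_b, cutoff = 0.5) {
  assert_scalar_number(cutoff, "cutoff", positive = TRUE)
  if (nrow(traj$xyz) == 0L) stop("empty ensemble", call. = FALSE)
  heavy <- select_atoms(traj, heavy_only = TRUE)
  sa <- intersect(as.integer(selection_a), heavy)
  sb <- intersect(as.integer(selection_b), heavy)
  if (length(sa) == 0L || length(sb) == 0L) {
    stop("a selection is empty after heavy-atom filtering", call. = FALSE)
  }
  res_b <- traj$atoms$residue_number[sb]
  residues <- sort(unique(res_b))
  nf <- nrow(traj$xyz)
  cutoff_A <- cutoff * ANGSTROM_PER_NM
  frame_contact <- logical(nf)
  res_hits <- matrix(FALSE, nrow = nf, ncol = length(residues))
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    xa <- co[sa, , drop = FALSE]
    xb <- co[sb, , drop = FALSE]
    a2 <- rowSums(xa^2)
    b2 <- rowSums(xb^2)
    d2 <- outer(a2, b2, "+") - 2 * tcrossprod(xa, xb)
    bmin <- sqrt(pmax(0, apply(d2, 2L, min)))  # per side-b atom
    frame_contact[f] <- any(bmin < cutoff_A)
    hits <- tapply(bmin < cutoff_A, res_b, any)
    res_hits[f, ] <- hits[as.character(residues)]
  }
  profile <- data.frame(residue_number = residues,
                        fraction = colMeans(res_hits))
  profile <- profile[order(-profile$fraction, profile$residue_number), ]
  rownames(profile) <- NULL
  list(fraction = mean(frame_contact), profile = profile, cutoff = cutoff,
       n_frames = nf)
}

#' Two-dimensional occupancy histogram of (d, d_g-ol)
#'
#' Counts frames into a 2-D grid. Frames outside the bin range go to
#' overflow counts, which are reported separately so that total mass is
#' conserved: `sum(counts) + sum(overflow) == n`. Log scaling is a
#' rendering choice only; stored counts are raw.
#'
#' @param d,dgol numeric vectors (nm), equal length.
#' @param d_breaks,dgol_breaks strictly increasing bin edges (nm).
#' @return list with `counts` (matrix, rows = d bins, cols = dgol bins),
#'   `d_breaks`, `dgol_breaks`, `overflow` (count of out-of-range frames),
#'   `n`.
#' @export
joint_histogram <- function(d, dgol, d_breaks, dgol_breaks) {
  if (length(d) != length(dgol)) {
    stop("`d` and `dgol` must have equal length", call. = FALSE)
  }
  if (is.unsorted(d_breaks, strictly = TRUE) ||
      is.unsorted(dgol_breaks, strictly = TRUE)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  nd <- length(d_breaks) - 1L
  ng <- length(dgol_breaks) - 1L
  # bins are [lo, hi); the last bin is closed on the right
  bi <- findInterval(d, d_breaks, rightmost.closed = TRUE)
  bj <- findInterval(dgol, dgol_breaks, rightmost.closed = TRUE)
  inside <- bi >= 1L & bi <= nd & bj >= 1L & bj <= ng
  counts <- matrix(0L, nrow = nd, ncol = ng)
  if (any(inside)) {
    tab <- table(factor(bi[inside], levels = seq_len(nd)),
                 factor(bj[inside], levels = seq_len(ng)))
    counts <- matrix(as.integer(tab), nrow = nd, ncol = ng)
  }
  overflow <- sum(!inside)
  if (overflow > 0L) {
    message(sprintf("joint_histogram: %d of %d frames fall outside the bin range",
                    overflow, length(d)))
  }
  list(counts = counts, d_breaks = d_breaks, dgol_breaks = dgol_breaks,
       overflow = overflow, n = length(d))
}

#' Write a 2-D histogram as TSV (rows = d bins, columns = dgol bins)
#' @param jh result of [joint_histogram()].
#' @param path output file.
#' @export
write_joint_histogram_tsv <- function(jh, path) {
  nd <- length(jh$d_breaks) - 1L
  ng <- length(jh$dgol_breaks) - 1L
  df <- data.frame(
    d_lo_nm = jh$d_breaks[seq_len(nd)],
    d_hi_nm = jh$d_breaks[-1L]
  )
  cnt <- as.data.frame(jh$counts)
  names(cnt) <- sprintf("dgol_%g_%g", jh$dgol_breaks[seq_len(ng)],
                        jh$dgol_breaks[-1L])
  utils::write.table(cbind(df, cnt), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
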