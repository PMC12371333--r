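#' Construct an atom table
#'
#' Atoms are stored as a tibble with one row per heavy atom. This is the
#' common currency of the package: structure readers, the synthetic
#' generator and the featurizer all produce or consume it.
#'
#' @param element Chemical element symbol (e.g. `"C"`, `"N"`, `"Zn"`).
#' @param x,y,z Cartesian coordinates in Angstrom.
#' @param partial_charge Partial charge in elementary charge units.
#' @param hybridization Integer in `1:3` (sp, sp2, sp3; 3 also encodes
#'   other/unknown).
#' @param heavy_valence Number of bonds to heavy atoms.
#' @param hetero_valence Number of bonds to heteroatoms (non C/H).
#' @param is_hydrophobic,is_aromatic,is_acceptor,is_donor,is_ring
#'   Pharmacophore flags.
#' @param role `"protein"` or `"ligand"`.
#' @param residue_id Chain + residue identifier; empty string for ligand
#'   atoms.
#'
#' @return A tibble with the 15 atom columns, validated.
#' @export
atom_table <- function(element, x, y, z,
                       partial_charge = 0,
                       hybridization = 3L,
                       heavy_valence = 0L,
                       hetero_valence = 0L,
                       is_hydrophobic = FALSE,
                       is_aromatic = FALSE,
                       is_acceptor = FALSE,
                       is_donor = FALSE,
                       is_ring = FALSE,
                       role = "protein",
                       residue_id = "") {
  atoms <- tibble::tibble(
    element = as.character(element),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    partial_charge = as.numeric(partial_charge),
    hybridization = as.integer(hybridization),
    heavy_valence = as.integer(heavy_valence),
    hetero_valence = as.integer(hetero_valence),
    is_hydrophobic = as.logical(is_hydrophobic),
    is_aromatic = as.logical(is_aromatic),
    is_acceptor = as.logical(is_acceptor),
    is_donor = as.logical(is_donor),
    is_ring = as.logical(is_ring),
    role = as.character(role),
    residue_id = as.character(residue_id)
  )
  validate_atoms(atoms)
}

atom_columns <- c(
  "element", "x", "y", "z", "partial_charge", "hybridization",
  "heavy_valence", "hetero_valence", "is_hydrophobic", "is_aromatic",
  "is_acceptor", "is_donor", "is_ring", "role", "residue_id"
)

validate_atoms <- function(atoms) {
  missing <- setdiff(atom_columns, names(atoms))
  assert_that(length(missing) == 0,
              paste("atom table missing columns:", paste(missing, collapse = ", ")))
  assert_that(all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)),
              "atom coordinates must be finite")
  assert_that(all(atoms$heavy_valence >= 0) && all(atoms$hetero_valence >= 0),
              "valence counts must be non-negative")
  assert_that(all(atoms$role %in% c("protein", "ligand")),
              "atom role must be 'protein' or 'ligand'")
  atoms
}

#' Single time point of a protein-ligand complex
#'
#' A `complex_frame` bundles an atom table with its provenance: which
#' complex it belongs to, which replicate simulation (the crystal pose is
#' replicate `-1` by convention), and the frame index within that
#' replicate. Only heavy atoms are kept; hydrogens never enter the
#' voxelization pipeline.
#'
#' @param atoms Atom tibble as built by [atom_table()].
#' @param complex_id Complex identifier string.
#' @param replicate_id Integer replicate index; `-1` marks the crystal pose.
#' @param frame_index Non-negative frame index within the replicate.
#' @param label_pk Binding affinity in pK units (-log10 Kd/Ki), or `NA`.
#'
#' @return An object of class `complex_frame`.
#' @export
complex_frame <- function(atoms, complex_id, replicate_id = -1L,
                          frame_index = 0L, label_pk = NA_real_) {
  atoms <- validate_atoms(tibble::as_tibble(atoms))
  structure(
    list(
      complex_id = as.character(complex_id),
      replicate_id = as.integer(replicate_id),
      frame_index = as.integer(frame_index),
      atoms = atoms,
      label_pk = as.numeric(label_pk)
    ),
    class = "complex_frame"
  )
}

#' @export
print.complex_frame <- function(x, ...) {
  cat(sprintf(
    "<complex_frame> %s  replicate %d  frame %d  (%d atoms: %d protein, %d ligand)%s\n",
    x$complex_id, x$replicate_id, x$frame_index, nrow(x$atoms),
    sum(x$atoms$role == "protein"), sum(x$atoms$role == "ligand"),
    if (is.finite(x$label_pk)) sprintf("  pK %.2f", x$label_pk) else ""
  ))
  invisible(x)
}

frame_coords <- function(frame) {
  as.matrix(frame$atoms[, c("x", "y", "z")])
}

set_frame_coords <- function(frame, coords) {
  frame$atoms$x <- coords[, 1]
  frame$atoms$y <- coords[, 2]
  frame$atoms$z <- coords[, 3]
  frame
}

#' Geometric center of the ligand heavy atoms
#'
#' The unweighted mean of the ligand heavy-atom coordinates. Used both to
#' define the binding pocket and to center voxelization boxes.
#'
#' @param frame A [complex_frame()].
#' @return Numeric 3-vector (Angstrom).
#' @export
ligand_center <- function(frame) {
  lig <- frame$atoms[frame$atoms$role == "ligand", ]
  if (nrow(lig) == 0) {
    abort(sprintf("complex '%s': no ligand atoms", frame$complex_id))
  }
  c(mean(lig$x), mean(lig$y), mean(lig$z))
}

#' Ordered frames of one replicate simulation
#'
#' A `trajectory` stores a shared atom roster (the topology) plus a
#' `T x n_atoms x 3` coordinate array, one slice per frame. All frames of
#' a trajectory share the complex id, replicate id and atom order; frame
#' indices are strictly increasing.
#'
#' @param atoms Template atom tibble (roster shared by all frames).
#' @param coords Numeric array of shape `(T, n_atoms, 3)`.
#' @param complex_id,replicate_id,label_pk Provenance, as in
#'   [complex_frame()].
#' @param frame_index Integer vector of length `T`; defaults to
#'   `0:(T-1)`.
#'
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(atoms, coords, complex_id, replicate_id = 0L,
                       label_pk = NA_real_, frame_index = NULL) {
  atoms <- validate_atoms(tibble::as_tibble(atoms))
  assert_that(length(dim(coords)) == 3 && dim(coords)[3] == 3,
              "coordinates must be 3-dimensional: array (T, n_atoms, 3)")
  assert_that(dim(coords)[2] == nrow(atoms),
              sprintf("coordinate array has %d atoms but roster has %d",
                      dim(coords)[2], nrow(atoms)))
  n_frames <- dim(coords)[1]
  if (is.null(frame_index)) frame_index <- seq_len(n_frames) - 1L
  assert_that(length(frame_index) == n_frames && all(diff(frame_index) > 0),
              "frame_index must be strictly increasing, one per frame")
  structure(
    list(
      complex_id = as.character(complex_id),
      replicate_id = as.integer(replicate_id),
      atoms = atoms,
      coords = coords,
      frame_index = as.integer(frame_index),
      label_pk = as.numeric(label_pk)
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s  replicate %d  %d frames x %d atoms%s\n",
              x$complex_id, x$replicate_id, n_frames(x), nrow(x$atoms),
              if (is.finite(x$label_pk)) sprintf("  pK %.2f", x$label_pk) else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame of a trajectory as a complex_frame
#' @param traj A [trajectory()].
#' @param t 1-based frame position.
#' @return A [complex_frame()].
#' @export
traj_frame <- function(traj, t) {
  assert_that(t >= 1 && t <= n_frames(traj), "frame position out of range")
  atoms <- traj$atoms
  atoms$x <- traj$coords[t, , 1]
  atoms$y <- traj$coords[t, , 2]
  atoms$z <- traj$coords[t, , 3]
  complex_frame(atoms, traj$complex_id, traj$replicate_id,
                traj$frame_index[t], traj$label_pk)
}

#' Build a trajectory from a list of frames
#'
#' All frames must share the atom roster (same elements, roles and order);
#' coordinates are stacked into the trajectory array.
#'
#' @param frames List of [complex_frame()] objects in time order.
#' @return A [trajectory()].
#' @export
trajectory_from_frames <- function(frames) {
  assert_that(length(frames) >= 1, "need at least one frame")
  f1 <- frames[[1]]
  n <- nrow(f1$atoms)
  roster <- f1$atoms[, c("element", "role", "residue_id")]
  coords <- array(0, c(length(frames), n, 3))
  idx <- integer(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    assert_that(nrow(f$atoms) == n &&
                  identical(f$atoms[, c("element", "role", "residue_id")], roster),
                "all frames must share the same atom roster")
    coords[i, , ] <- frame_coords(f)
    idx[i] <- f$frame_index
  }
  trajectory(f1$atoms, coords, f1$complex_id, f1$replicate_id,
             f1$label_pk, frame_index = idx)
}

#' Treat a crystal pose as a single-frame trajectory
#'
#' Keeps every downstream path uniform: the crystal pose is a 1-frame
#' trajectory with replicate id `-1`.
#'
#' @param frame A [complex_frame()].
#' @return A [trajectory()] of length 1.
#' @export
as_trajectory <- function(frame) {
  coords <- array(frame_coords(frame), c(1, nrow(frame$atoms), 3))
  trajectory(frame$atoms, coords, frame$complex_id, -1L,
             frame$label_pk, frame_index = frame$frame_index)
}
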