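#' Names of the 19 atomic feature channels
#'
#' Nine one-hot atom-type flags (B, C, N, O, P, S, Se, halogen, metal),
#' hybridization (1-3), heavy-atom valence, heteroatom valence, five
#' pharmacophore flags (hydrophobic, aromatic, acceptor, donor, ring),
#' partial charge, and the molecule-type channel (-1 ligand, +1 protein).
#' The order is frozen and written into every grid dataset's metadata.
#'
#' @return Character vector of length 19.
#' @export
feature_channels <- function() {
  c("type_B", "type_C", "type_N", "type_O", "type_P", "type_S", "type_Se",
    "type_halogen", "type_metal",
    "hybridization", "heavy_valence", "hetero_valence",
    "hydrophobic", "aromatic", "acceptor", "donor", "ring",
    "partial_charge", "moltype")
}

halogen_elements <- c("F", "Cl", "Br", "I")
onehot_elements <- c("B", "C", "N", "O", "P", "S", "Se")

.featurize_cache <- new.env(parent = emptyenv())

#' Encode atoms as 19-channel feature vectors
#'
#' Vectorized over an atom table. Halogens (F, Cl, Br, I) share one type
#' flag; any element outside \{B, C, N, O, P, S, Se, H\} and outside the
#' halogens is classed as metal. Hydrogen is never encoded (heavy atoms
#' only); if present it receives all-zero type flags and should have been
#' filtered upstream.
#'
#' @param atoms Atom tibble ([atom_table()]).
#' @return Numeric matrix `n_atoms x 19`, columns ordered as
#'   [feature_channels()].
#' @export
encode_atoms <- function(atoms) {
  atoms <- validate_atoms(atoms)
  n <- nrow(atoms)
  m <- matrix(0, n, 19, dimnames = list(NULL, feature_channels()))
  el <- atoms$element
  for (i in seq_along(onehot_elements)) {
    m[el == onehot_elements[i], i] <- 1
  }
  m[el %in% halogen_elements, "type_halogen"] <- 1
  is_metal <- !(el %in% c(onehot_elements, halogen_elements, "H"))
  m[is_metal, "type_metal"] <- 1
  m[, "hybridization"] <- atoms$hybridization
  m[, "heavy_valence"] <- atoms$heavy_valence
  m[, "hetero_valence"] <- atoms$hetero_valence
  m[, "hydrophobic"] <- as.numeric(atoms$is_hydrophobic)
  m[, "aromatic"] <- as.numeric(atoms$is_aromatic)
  m[, "acceptor"] <- as.numeric(atoms$is_acceptor)
  m[, "donor"] <- as.numeric(atoms$is_donor)
  m[, "ring"] <- as.numeric(atoms$is_ring)
  m[, "partial_charge"] <- atoms$partial_charge
  m[, "moltype"] <- ifelse(atoms$role == "ligand", -1, 1)
  m
}

#' Select binding-pocket residues around the ligand
#'
#' The pocket is the set of protein residues having at least one heavy
#' atom within `radius_A` (inclusive) of the geometric center of the
#' ligand heavy atoms. The selection is made once on the crystal pose and
#' reused for every frame and replicate of that complex.
#'
#' @param crystal_frame A [complex_frame()] holding the crystal pose.
#' @param radius_A Cutoff distance in Angstrom (default 12).
#' @return Character vector of selected `residue_id`s.
#' @export
extract_pocket <- function(crystal_frame, radius_A = 12) {
  center <- ligand_center(crystal_frame)
  prot <- crystal_frame$atoms[crystal_frame$atoms$role == "protein", ]
  if (nrow(prot) == 0) return(character(0))
  d <- dist_to_point(as.matrix(prot[, c("x", "y", "z")]), center)
  sort(unique(prot$residue_id[d <= radius_A]))
}

#' Restrict a frame to its pocket residues
#'
#' Keeps all ligand atoms plus protein atoms whose residue is in the
#' pocket selection.
#'
#' @param frame A [complex_frame()].
#' @param pocket_residues Residue ids from [extract_pocket()].
#' @return A [complex_frame()] with the reduced atom table.
#' @export
restrict_to_pocket <- function(frame, pocket_residues) {
  keep <- frame$atoms$role == "ligand" | frame$atoms$residue_id %in% pocket_residues
  frame$atoms <- frame$atoms[keep, ]
  frame
}

#' Remove one molecular partner from a frame
#'
#' Used by the bias-gap protocol: models are retrained on frames holding
#' only the protein or only the ligand, and the drop in test correlation
#' measures how much the model relied on the removed partner. Box
#' centering metadata is untouched, so an `"ligand_only"` frame still gets
#' pocket-centered boxes unless ligand tracking is requested explicitly.
#'
#' @param frame A [complex_frame()].
#' @param keep One of `"complex"`, `"protein_only"`, `"ligand_only"`.
#' @return The masked [complex_frame()].
#' @export
mask_partner <- function(frame, keep = c("complex", "protein_only", "ligand_only")) {
  keep <- match.arg(keep)
  if (keep == "complex") return(frame)
  role <- if (keep == "protein_only") "protein" else "ligand"
  frame$atoms <- frame$atoms[frame$atoms$role == role, ]
  assert_that(nrow(frame$atoms) > 0,
              sprintf("complex '%s': mask '%s' leaves no atoms",
                      frame$complex_id, keep))
  frame
}

#' Voxel grid around the binding site
#'
#' @param values Numeric array `(C, D, D, D)`.
#' @param edge_A Box edge length, Angstrom.
#' @param resolution_A Voxel edge, Angstrom; `D = edge_A / resolution_A`
#'   must be an integer.
#' @param origin Minimum corner of the box, 3-vector (Angstrom).
#' @param centering `"pocket"` (fixed crystal-ligand center) or
#'   `"ligand_tracking"` (recentered every frame).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, edge_A, resolution_A, origin,
                       centering = "pocket") {
  d <- edge_A / resolution_A
  assert_that(abs(d - round(d)) < 1e-9,
              sprintf("edge %g not divisible by resolution %g", edge_A, resolution_A))
  d <- as.integer(round(d))
  assert_that(length(dim(values)) == 4 && all(dim(values)[2:4] == d),
              "grid values must be (C, D, D, D)")
  structure(
    list(values = values, edge_A = edge_A, resolution_A = resolution_A,
         origin = as.numeric(origin), centering = centering,
         channels = feature_channels()),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d channels, %d^3 voxels (%.3g A edge, %.3g A resolution, %s-centered), %d occupied\n",
              d[1], d[2], x$edge_A, x$resolution_A, x$centering,
              sum(colSums(matrix(x$values != 0, d[1])) > 0)))
  invisible(x)
}

#' Voxelize one frame into a cubic feature grid
#'
#' A cubic box of side `edge_A` is placed around the binding site and
#' discretized into voxels of side `resolution_A`. Each heavy atom inside
#' the box contributes its 19-feature vector to the voxel containing it;
#' atoms sharing a voxel are summed elementwise, and atoms outside the
#' box are dropped. Voxel cells are half-open `[k, k+1)` from the box
#' minimum corner, so an atom exactly on the maximum face is dropped;
#' this convention makes right-angle rotation equivariance exact.
#'
#' @param frame A [complex_frame()].
#' @param centering `"pocket"` or `"ligand_tracking"`. In `"pocket"` mode
#'   the caller normally supplies the crystal-pose ligand center via
#'   `center` so the box stays fixed across frames; when `center` is
#'   `NULL` the current frame's ligand center is used (which is the
#'   crystal center when the frame is the crystal pose).
#' @param edge_A Box edge, Angstrom (default 25).
#' @param resolution_A Voxel edge, Angstrom (default 1).
#' @param center Optional fixed box center (3-vector, Angstrom).
#' @return A [voxel_grid()].
#' @export
make_box <- function(frame, centering = c("pocket", "ligand_tracking"),
                     edge_A = 25, resolution_A = 1, center = NULL) {
  centering <- match.arg(centering)
  assert_that(nrow(frame$atoms) > 0, "cannot voxelize an empty frame")
  d <- edge_A / resolution_A
  assert_that(abs(d - round(d)) < 1e-9,
              sprintf("edge %g not divisible by resolution %g", edge_A, resolution_A))
  d <- as.integer(round(d))
  if (is.null(center) || centering == "ligand_tracking") {
    center <- ligand_center(frame)
  }
  origin <- center - edge_A / 2
  coords <- frame_coords(frame)
  idx <- floor(sweep(coords, 2, origin) / resolution_A)
  inside <- idx[, 1] >= 0 & idx[, 1] < d &
    idx[, 2] >= 0 & idx[, 2] < d &
    idx[, 3] >= 0 & idx[, 3] < d
  values <- array(0, c(19L, d, d, d))
  if (any(inside)) {
    feats <- encode_atoms(frame$atoms[inside, , drop = FALSE])
    ii <- idx[inside, , drop = FALSE]
    # linear voxel offset in the (D, D, D) block, 0-based; colliding
    # atoms are summed elementwise by rowsum()
    lin <- ii[, 1] + d * (ii[, 2] + d * ii[, 3])
    summed <- rowsum(feats, lin, reorder = FALSE)
    vox <- as.numeric(rownames(summed))
    values[rep(1:19, nrow(summed)) + 19 * rep(vox, each = 19)] <- t(summed)
  }
  voxel_grid(values, edge_A, resolution_A, origin, centering)
}

#' Ordered sequence of voxel grids (the 4D network input)
#'
#' @param values Numeric array `(T, C, D, D, D)`.
#' @param edge_A,resolution_A,centering As in [voxel_grid()].
#' @param label_pk Affinity label in pK units, or `NA`.
#' @return An object of class `voxel_sequence`.
#' @export
voxel_sequence <- function(values, edge_A, resolution_A,
                           centering = "pocket", label_pk = NA_real_) {
  assert_that(length(dim(values)) == 5, "sequence values must be (T, C, D, D, D)")
  structure(
    list(values = values, edge_A = edge_A, resolution_A = resolution_A,
         centering = centering, channels = feature_channels(),
         label_pk = as.numeric(label_pk)),
    class = "voxel_sequence"
  )
}

#' @export
print.voxel_sequence <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_sequence> %d frames x %d channels x %d^3 voxels (%s-centered)%s\n",
              d[1], d[2], d[3], x$centering,
              if (is.finite(x$label_pk)) sprintf("  pK %.2f", x$label_pk) else ""))
  invisible(x)
}

#' Voxelize every frame of a trajectory
#'
#' In `"pocket"` mode a single box center (by default the ligand
#' geometric center of the first frame, or an explicitly supplied crystal
#' center) is reused for all frames; in `"ligand_tracking"` mode the box
#' is recentered on the ligand at every frame. When a rotation is given,
#' the same rotation about the same pivot is applied to every frame
#' before voxelization.
#'
#' @param traj A [trajectory()].
#' @inheritParams make_box
#' @param rotation Optional [rotation()] applied consistently to all
#'   frames.
#' @param pivot Rotation pivot; defaults to the box center.
#' @return A [voxel_sequence()].
#' @export
voxelize_trajectory <- function(traj, centering = c("pocket", "ligand_tracking"),
                                edge_A = 25, resolution_A = 1, center = NULL,
                                rotation = NULL, pivot = NULL) {
  centering <- match.arg(centering)
  t_len <- n_frames(traj)
  if (centering == "pocket" && is.null(center)) {
    center <- ligand_center(traj_frame(traj, 1))
  }
  if (!is.null(rotation) && is.null(pivot)) {
    pivot <- if (centering == "pocket") center else ligand_center(traj_frame(traj, 1))
  }
  d <- as.integer(round(edge_A / resolution_A))
  values <- array(0, c(t_len, 19L, d, d, d))
  for (t in seq_len(t_len)) {
    fr <- traj_frame(traj, t)
    if (!is.null(rotation)) fr <- apply_rotation(fr, rotation, pivot)
    g <- make_box(fr, centering, edge_A, resolution_A, center = center)
    values[t, , , , ] <- g$values
  }
  voxel_sequence(values, edge_A, resolution_A, centering, traj$label_pk)
}

# ---- rotations ---------------------------------------------------------

#' A proper rotation of 3-space
#'
#' @param mat Orthonormal 3x3 matrix with determinant +1.
#' @param tag Systematic index `0:23` for the right-angle rotations, or
#'   `"random"` for a continuous draw.
#' @return An object of class `rotation`.
#' @export
rotation <- function(mat, tag = "random") {
  mat <- as.matrix(mat)
  assert_that(all(dim(mat) == c(3, 3)), "rotation matrix must be 3x3")
  assert_that(max(abs(crossprod(mat) - diag(3))) < 1e-10,
              "rotation matrix is not orthonormal")
  assert_that(abs(det(mat) - 1) < 1e-8, "rotation must be proper (det +1)")
  structure(list(mat = mat, tag = tag), class = "rotation")
}

#' @export
print.rotation <- function(x, ...) {
  cat(sprintf("<rotation> tag %s\n", x$tag))
  print(unname(x$mat))
  invisible(x)
}

#' Enumerate the 24 right-angle rotations of the cube
#'
#' The proper octahedral rotation group: every orthonormal signed
#' permutation matrix with determinant +1. The identity comes first; the
#' set is closed under composition.
#'
#' @return List of 24 [rotation()] objects, tags `0:23`.
#' @export
enumerate_rotations <- function() {
  if (!is.null(.featurize_cache$rotations)) return(.featurize_cache$rotations)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      m <- matrix(0, 3, 3)
      signs <- c(s1, s2, s3)
      for (j in 1:3) m[j, p[j]] <- signs[j]
      if (abs(det(m) - 1) < 1e-12) out[[length(out) + 1]] <- m
    }
  }
  # identity first, then a stable order over the rest
  is_id <- vapply(out, function(m) all(m == diag(3)), logical(1))
  out <- c(out[is_id], out[!is_id])
  rots <- purrr::imap(out, function(m, i) rotation(m, tag = i - 1L))
  .featurize_cache$rotations <- rots
  rots
}

#' Draw one random rotation
#'
#' The training default draws uniformly among the 24 right-angle
#' rotations, which keeps voxel grids lossless under rotation; a
#' continuous uniform rotation (via QR of a Gaussian matrix, sign-fixed
#' to det +1) is available as an option.
#'
#' @param kind `"right_angle"` (default) or `"so3"`.
#' @return A [rotation()].
#' @export
random_rotation <- function(kind = c("right_angle", "so3")) {
  kind <- match.arg(kind)
  if (kind == "right_angle") {
    rots <- enumerate_rotations()
    rots[[sample.int(24, 1)]]
  } else {
    qr_ <- qr(matrix(rnorm(9), 3))
    q <- qr.Q(qr_)
    d <- diag(sign(diag(qr.R(qr_))))
    m <- q %*% d
    if (det(m) < 0) m <- -m  # -I maps O(3) Haar onto SO(3) Haar
    rotation(m, tag = "random")
  }
}

#' Rotate a frame about a pivot
#'
#' Coordinates map as `x' = R (x - pivot) + pivot`; features are
#' untouched, so all pairwise distances are preserved.
#'
#' @param frame A [complex_frame()].
#' @param rot A [rotation()] (or bare 3x3 matrix, validated).
#' @param pivot 3-vector, Angstrom.
#' @return The rotated [complex_frame()].
#' @export
apply_rotation <- function(frame, rot, pivot = c(0, 0, 0)) {
  if (!inherits(rot, "rotation")) rot <- rotation(rot)
  coords <- frame_coords(frame)
  rotated <- sweep(tcrossprod(sweep(coords, 2, pivot), rot$mat), 2, pivot, "+")
  set_frame_coords(frame, rotated)
}

#' Apply a right-angle rotation directly to a voxel grid
#'
#' For the 24 signed-permutation rotations about the box center,
#' rotating the underlying frame and re-voxelizing is exactly equivalent
#' to permuting/flipping the grid axes; this helper performs that index
#' operation, which is how systematic rotation augmentation is done
#' without touching coordinates.
#'
#' @param grid A [voxel_grid()].
#' @param rot A right-angle [rotation()] (signed permutation matrix).
#' @return The rotated [voxel_grid()].
#' @export
rotate_grid <- function(grid, rot) {
  if (!inherits(rot, "rotation")) rot <- rotation(rot)
  m <- round(rot$mat)
  assert_that(all(m %in% c(-1, 0, 1)) && all(colSums(abs(m)) == 1),
              "rotate_grid requires a right-angle (signed permutation) rotation")
  d <- dim(grid$values)[2]
  # output axis j draws from input axis p(j) with sign s(j):
  # i'_j = i_{p(j)} if s = +1, else D - 1 - i_{p(j)}
  src_axis <- integer(3)
  src_sign <- integer(3)
  for (j in 1:3) {
    src_axis[j] <- which(m[j, ] != 0)
    src_sign[j] <- m[j, src_axis[j]]
  }
  # invert: for each output axis, which input index vector to gather
  out <- array(0, dim(grid$values))
  idx <- vector("list", 3)
  for (j in 1:3) idx[[j]] <- if (src_sign[j] == 1) seq_len(d) else rev(seq_len(d))
  perm <- c(1, 1 + src_axis)
  permuted <- aperm(grid$values, perm)
  out <- permuted[, idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  voxel_grid(out, grid$edge_A, grid$resolution_A, grid$origin, grid$centering)
}
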