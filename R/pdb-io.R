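# Structure input. PDB parsing is delegated to bio3d; this layer assigns
# roles (protein vs ligand), drops hydrogens, and attaches per-atom
# feature annotations from a sidecar table or a deterministic fallback.

standard_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HOH", "WAT"
)

#' Read a protein-ligand complex from a PDB file
#'
#' Parses a single-model PDB, keeps heavy atoms only, and assigns roles:
#' the ligand is the residue named by `ligand_resname`; when that is
#' `NULL` every HETATM residue outside the standard amino acids and
#' water is taken as ligand. Per-atom feature annotations (partial
#' charge, hybridization, valences, pharmacophore flags) come from a
#' sidecar CSV keyed by atom serial number; without one, a deterministic
#' geometric fallback annotator is applied ([annotate_fallback()]).
#'
#' @param structure_path Path to a PDB file.
#' @param annotation_path Optional CSV with columns `eleno`,
#'   `partial_charge`, `hybridization`, `heavy_valence`,
#'   `hetero_valence`, `is_hydrophobic`, `is_aromatic`, `is_acceptor`,
#'   `is_donor`, `is_ring`.
#' @param ligand_resname Residue name of the ligand (e.g. `"LIG"`).
#' @param complex_id Identifier; defaults to the file stem.
#' @param label_pk Optional affinity label.
#' @return A [complex_frame()] (crystal pose: replicate `-1`, frame 0).
#' @export
read_complex <- function(structure_path, annotation_path = NULL,
                         ligand_resname = NULL, complex_id = NULL,
                         label_pk = NA_real_) {
  complex_id <- complex_id %||% sub("\\.[^.]*$", "", basename(structure_path))
  pdb <- tryCatch(
    bio3d::read.pdb(structure_path, verbose = FALSE),
    error = function(e) abort(sprintf("cannot parse '%s': %s", structure_path,
                                      conditionMessage(e)))
  )
  atoms <- pdb_to_atoms(pdb$atom, complex_id, ligand_resname)
  atoms <- attach_annotations(atoms, annotation_path)
  complex_frame(atoms[, atom_columns], complex_id, replicate_id = -1L,
                frame_index = 0L, label_pk = label_pk)
}

pdb_to_atoms <- function(atom_df, complex_id, ligand_resname = NULL) {
  elesy <- trimws(atom_df$elesy)
  elesy[is.na(elesy) | elesy == ""] <- substr(trimws(atom_df$elety[is.na(elesy) | elesy == ""]), 1, 1)
  heavy <- elesy != "H"
  atom_df <- atom_df[heavy, , drop = FALSE]
  elesy <- elesy[heavy]
  resid <- trimws(atom_df$resid)
  if (!is.null(ligand_resname)) {
    is_lig <- resid == ligand_resname
  } else {
    is_lig <- atom_df$type == "HETATM" & !(resid %in% standard_residues)
  }
  is_water <- resid %in% c("HOH", "WAT")
  keep <- !is_water
  atom_df <- atom_df[keep, , drop = FALSE]
  elesy <- elesy[keep]
  is_lig <- is_lig[keep]
  if (!any(is_lig)) {
    abort(sprintf("complex '%s': no ligand atoms (no matching HETATM residue)",
                  complex_id))
  }
  tibble::tibble(
    eleno = atom_df$eleno,
    element = normalize_element(elesy),
    x = atom_df$x, y = atom_df$y, z = atom_df$z,
    partial_charge = 0,
    hybridization = 3L,
    heavy_valence = 0L,
    hetero_valence = 0L,
    is_hydrophobic = FALSE, is_aromatic = FALSE, is_acceptor = FALSE,
    is_donor = FALSE, is_ring = FALSE,
    role = ifelse(is_lig, "ligand", "protein"),
    residue_id = ifelse(is_lig, "",
                        paste0(atom_df$chain, ":", trimws(atom_df$resid),
                               atom_df$resno))
  )
}

normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

attach_annotations <- function(atoms, annotation_path) {
  if (is.null(annotation_path)) {
    return(annotate_fallback(atoms))
  }
  ann <- readr::read_csv(annotation_path, show_col_types = FALSE)
  assert_that("eleno" %in% names(ann),
              "annotation table must carry an 'eleno' key column")
  ann_cols <- intersect(
    c("partial_charge", "hybridization", "heavy_valence", "hetero_valence",
      "is_hydrophobic", "is_aromatic", "is_acceptor", "is_donor", "is_ring"),
    names(ann)
  )
  atoms <- dplyr::rows_update(
    atoms, ann[, c("eleno", ann_cols)],
    by = "eleno", unmatched = "ignore"
  )
  atoms$hybridization <- as.integer(atoms$hybridization)
  atoms$heavy_valence <- as.integer(atoms$heavy_valence)
  atoms$hetero_valence <- as.integer(atoms$hetero_valence)
  atoms
}

#' Deterministic fallback feature annotator
#'
#' When no sidecar annotation table accompanies a structure, bonds are
#' perceived from heavy-atom distances (pairs closer than 1.25x the sum
#' of covalent radii), valences counted from them, and simple rules set
#' the pharmacophore flags: hydrophobic = carbon with no bonded
#' heteroatom, acceptor = N/O/F, donor = N/O. Hybridization defaults to
#' 3, aromatic/ring to FALSE, partial charges to 0. This keeps toy
#' fixtures self-contained; production use supplies real annotations.
#'
#' @param atoms Atom tibble (coordinates and elements populated).
#' @return The tibble with annotation columns filled.
#' @export
annotate_fallback <- function(atoms) {
  radii <- c(B = 0.84, C = 0.76, N = 0.71, O = 0.66, P = 1.07, S = 1.05,
             Se = 1.20, F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39)
  r <- radii[atoms$element]
  r[is.na(r)] <- 1.4  # metals and unknowns
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(atoms)
  if (n > 1) {
    d <- cross_dist(xyz, xyz)
    cutoff <- 1.25 * outer(r, r, "+")
    bonded <- d < cutoff & d > 1e-6
    is_hetero <- !(atoms$element %in% c("C", "H"))
    atoms$heavy_valence <- as.integer(rowSums(bonded))
    atoms$hetero_valence <- as.integer(bonded %*% is_hetero)
  }
  atoms$hybridization <- 3L
  atoms$is_hydrophobic <- atoms$element == "C" & atoms$hetero_valence == 0
  atoms$is_acceptor <- atoms$element %in% c("N", "O", "F")
  atoms$is_donor <- atoms$element %in% c("N", "O")
  atoms$is_aromatic <- FALSE
  atoms$is_ring <- FALSE
  atoms$partial_charge <- 0
  atoms
}

#' Read a trajectory from a multi-model PDB or a container file
#'
#' Multi-model PDBs are parsed with bio3d; every MODEL must share the
#' atom roster, and the model order defines the frame index. Files
#' written by [write_trajectory()] are read back exactly.
#'
#' @param path `.pdb` file with MODEL records, or a container file.
#' @param ligand_resname,annotation_path As in [read_complex()] (PDB
#'   input only).
#' @param complex_id,replicate_id,label_pk Provenance overrides (PDB
#'   input only).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, ligand_resname = NULL,
                            annotation_path = NULL, complex_id = NULL,
                            replicate_id = 0L, label_pk = NA_real_) {
  if (!grepl("\\.pdb$", path, ignore.case = TRUE)) {
    return(read_trajectory_container(path))
  }
  complex_id <- complex_id %||% sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) abort(sprintf("cannot parse '%s': %s", path,
                                      conditionMessage(e)))
  )
  atoms <- pdb_to_atoms(pdb$atom, complex_id, ligand_resname)
  atoms <- attach_annotations(atoms, annotation_path)
  n_all <- nrow(pdb$atom)
  n_models <- nrow(pdb$xyz)
  xyz <- array(t(pdb$xyz), c(3, n_all, n_models))
  # subset to the heavy, non-water atoms kept by pdb_to_atoms
  keep <- pdb$atom$eleno %in% atoms$eleno
  assert_that(sum(keep) == nrow(atoms), "atom roster mismatch across models")
  coords <- aperm(xyz[, keep, , drop = FALSE], c(3, 2, 1))
  trajectory(atoms[, atom_columns], coords, complex_id, replicate_id, label_pk)
}
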