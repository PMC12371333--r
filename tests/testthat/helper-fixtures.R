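# Small builders shared across the suite. Everything is generated in
# code; no fixture files.

# a frame with explicit coordinates: protein atoms first, then ligand
toy_frame <- function(protein_xyz, ligand_xyz,
                      protein_res = paste0("A:RES", seq_len(nrow(protein_xyz))),
                      complex_id = "toy", label_pk = NA_real_) {
  atoms <- dplyr::bind_rows(
    atom_table("C", protein_xyz[, 1], protein_xyz[, 2], protein_xyz[, 3],
               role = "protein", residue_id = protein_res),
    atom_table("C", ligand_xyz[, 1], ligand_xyz[, 2], ligand_xyz[, 3],
               role = "ligand")
  )
  complex_frame(atoms, complex_id, label_pk = label_pk)
}

# a randomized frame for property tests: n_prot protein + n_lig ligand
# atoms in a ball of the given radius, mixed elements and annotations
random_frame <- function(n_prot = 30, n_lig = 6, radius = 10,
                         complex_id = "rnd") {
  n <- n_prot + n_lig
  xyz <- matrix(runif(n * 3, -radius, radius), n, 3)
  atoms <- atom_table(
    element = sample(c("C", "N", "O", "S", "Cl", "Zn"), n, replace = TRUE),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    partial_charge = round(rnorm(n, 0, 0.3), 3),
    hybridization = sample(1:3, n, replace = TRUE),
    heavy_valence = sample(0:4, n, replace = TRUE),
    hetero_valence = sample(0:2, n, replace = TRUE),
    is_hydrophobic = runif(n) < 0.5,
    is_aromatic = runif(n) < 0.3,
    is_acceptor = runif(n) < 0.3,
    is_donor = runif(n) < 0.3,
    is_ring = runif(n) < 0.3,
    role = rep(c("protein", "ligand"), c(n_prot, n_lig)),
    residue_id = c(paste0("A:R", ceiling(seq_len(n_prot) / 3)), rep("", n_lig))
  )
  complex_frame(atoms, complex_id)
}

# 3-atom PDB text: two protein atoms, one ligand heavy atom (+ optional H)
toy_pdb_lines <- function(with_hydrogens = FALSE) {
  lines <- c(
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       2.000   0.500   0.000  1.00  0.00           C",
    "HETATM    3  C1  LIG A  99       0.000   0.000   1.000  1.00  0.00           C"
  )
  if (with_hydrogens) {
    lines <- c(lines,
      "ATOM      4  H   ALA A   1       1.100   0.100   0.000  1.00  0.00           H",
      "HETATM    5  H1  LIG A  99       0.100   0.000   1.100  1.00  0.00           H")
  }
  c(lines, "END")
}

toy_manifest <- function(n = 10, seed = 1) {
  ids <- sprintf("cpx%02d", seq_len(n))
  sp <- make_splits(ids, val_fraction = 0.2, test_fraction = 0.2, seed = seed)
  manifest(ids, label_pk = seq(3, 10, length.out = n),
           split = sp$split[match(ids, sp$complex_id)],
           protein_family = rep(c("kinase", "protease"), length.out = n),
           cluster_id = paste0("cl", ceiling(seq_len(n) / 3)))
}

# tiny synthetic dataset used by several modules; cached per session
tiny_synthetic <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_synthetic_set(
        synthetic_spec(n_complexes = 12, n_replicates = 2, n_frames = 4))
    }
    cache
  }
})
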