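# Synthetic desk-scale stand-in for an MD-trajectory affinity corpus.
# Each toy complex is a rigid pseudo-pocket shell of atoms around the
# origin plus a small ligand inside it. The affinity label is a known
# linear function of the number of ligand-pocket contact pairs, so the
# signal is recoverable and a brute-force oracle is exact. Replicate
# trajectories move the ligand as a rigid body on a Gaussian random walk
# whose step size grows as the label drops, planting the empirical
# relationship between low affinity and ligand instability.

#' Specification of a synthetic dataset
#'
#' Defaults mirror the shape of the real corpus (10 replicate
#' simulations of 50 frames per complex; 500 frames per complex in
#' total) at desk scale. The planted signal is
#' `label_pk = a + b * n_contacts + N(0, sigma)`, clipped to `[0, 14]`,
#' where `n_contacts` counts ligand-pocket atom pairs within
#' `contact_radius_A`. Ligand drift follows a per-frame random walk with
#' step `sigma_drift(pk) = drift_s0 + drift_s1 * max(0, pk_mid - pk)`.
#'
#' @param n_complexes Number of complexes (default 120).
#' @param n_replicates Replicate simulations per complex (default 10).
#' @param n_frames Frames per simulation (default 50).
#' @param pocket_n_atoms Atoms on the pocket shell.
#' @param pocket_radius_range Shell radius draw, Angstrom.
#' @param ligand_n_range Ligand heavy-atom count range.
#' @param ligand_radius_A Ligand atoms are sampled in this ball.
#' @param contact_radius_A Contact-pair cutoff, Angstrom.
#' @param signal_a,signal_b,signal_sigma Planted affinity: intercept
#'   (pK), slope (pK per contact pair), noise SD (pK).
#' @param drift_s0,drift_s1,pk_mid Ligand random-walk step parameters
#'   (Angstrom/frame, Angstrom/frame/pK, pK).
#' @param pocket_jitter_A Per-frame iid pocket atom jitter SD.
#' @param val_fraction,test_fraction Complex-level split fractions.
#' @param seed Base seed; everything downstream derives from it.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_complexes = 120L, n_replicates = 10L,
                           n_frames = 50L,
                           pocket_n_atoms = 60L,
                           pocket_radius_range = c(5.5, 8.5),
                           ligand_n_range = c(8L, 16L),
                           ligand_radius_A = 3,
                           contact_radius_A = 6,
                           signal_a = 2, signal_b = 0.025,
                           signal_sigma = 0.3,
                           drift_s0 = 0.15, drift_s1 = 0.01, pk_mid = 7,
                           pocket_jitter_A = 0.05,
                           val_fraction = 0.2, test_fraction = 0.2,
                           seed = 20240801L) {
  assert_that(signal_sigma >= 0 && drift_s0 >= 0 && drift_s1 >= 0 &&
                pocket_jitter_A >= 0, "all sigmas must be >= 0")
  structure(
    list(n_complexes = as.integer(n_complexes),
         n_replicates = as.integer(n_replicates),
         n_frames = as.integer(n_frames),
         pocket_n_atoms = as.integer(pocket_n_atoms),
         pocket_radius_range = pocket_radius_range,
         ligand_n_range = as.integer(ligand_n_range),
         ligand_radius_A = ligand_radius_A,
         contact_radius_A = contact_radius_A,
         signal_a = signal_a, signal_b = signal_b,
         signal_sigma = signal_sigma,
         drift_s0 = drift_s0, drift_s1 = drift_s1, pk_mid = pk_mid,
         pocket_jitter_A = pocket_jitter_A,
         val_fraction = val_fraction, test_fraction = test_fraction,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

runif_sphere <- function(n, radius) {
  v <- matrix(rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2)) * radius
}

runif_ball <- function(n, radius) {
  v <- matrix(rnorm(3 * n), n, 3)
  u <- runif(n)^(1 / 3)
  v / sqrt(rowSums(v^2)) * (radius * u)
}

#' Generate one synthetic complex
#'
#' Pocket atoms sit on a spherical shell around the origin (grouped into
#' 3-atom pseudo-residues); ligand atoms are sampled inside. All
#' annotation fields are drawn deterministically from the seed. The
#' label comes from the planted contact formula; the realized contact
#' count is attached as attribute `"n_contacts"`.
#'
#' @param spec A [synthetic_spec()].
#' @param index Complex index (drives the derived seed and the id).
#' @return A labeled [complex_frame()] (crystal pose).
#' @export
generate_complex <- function(spec, index = 1L) {
  id <- sprintf("syn%04d", index)
  withr::with_seed(derive_seed(spec$seed, 1, index), {
    rp <- runif(1, spec$pocket_radius_range[1], spec$pocket_radius_range[2])
    np <- spec$pocket_n_atoms
    pocket_xyz <- runif_sphere(np, rp)
    nl <- sample(seq(spec$ligand_n_range[1], spec$ligand_n_range[2]), 1)
    ligand_xyz <- runif_ball(nl, spec$ligand_radius_A)
    pocket <- tibble::tibble(
      element = sample(c("C", "N", "O", "S"), np, replace = TRUE,
                       prob = c(0.6, 0.17, 0.17, 0.06)),
      x = pocket_xyz[, 1], y = pocket_xyz[, 2], z = pocket_xyz[, 3],
      partial_charge = round(rnorm(np, 0, 0.2), 4),
      hybridization = sample(1:3, np, replace = TRUE, prob = c(0.1, 0.3, 0.6)),
      heavy_valence = sample(1:4, np, replace = TRUE),
      hetero_valence = sample(0:2, np, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
      is_hydrophobic = runif(np) < 0.4,
      is_aromatic = runif(np) < 0.2,
      is_acceptor = runif(np) < 0.3,
      is_donor = runif(np) < 0.3,
      is_ring = runif(np) < 0.25,
      role = "protein",
      residue_id = paste0("A:RES", ceiling(seq_len(np) / 3))
    )
    ligand <- tibble::tibble(
      element = sample(c("C", "N", "O"), nl, replace = TRUE,
                       prob = c(0.7, 0.15, 0.15)),
      x = ligand_xyz[, 1], y = ligand_xyz[, 2], z = ligand_xyz[, 3],
      partial_charge = round(rnorm(nl, 0, 0.2), 4),
      hybridization = sample(1:3, nl, replace = TRUE),
      heavy_valence = sample(1:4, nl, replace = TRUE),
      hetero_valence = sample(0:2, nl, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
      is_hydrophobic = runif(nl) < 0.4,
      is_aromatic = runif(nl) < 0.3,
      is_acceptor = runif(nl) < 0.3,
      is_donor = runif(nl) < 0.3,
      is_ring = runif(nl) < 0.4,
      role = "ligand",
      residue_id = ""
    )
    n_contacts <- sum(cross_dist(ligand_xyz, pocket_xyz) <= spec$contact_radius_A)
    label <- spec$signal_a + spec$signal_b * n_contacts +
      rnorm(1, 0, spec$signal_sigma)
    label <- min(max(label, 0), 14)
    frame <- complex_frame(dplyr::bind_rows(pocket, ligand), id,
                           replicate_id = -1L, frame_index = 0L,
                           label_pk = label)
    attr(frame, "n_contacts") <- n_contacts
    frame
  })
}

#' Generate one replicate trajectory for a complex
#'
#' Frame 1 is the input pose. The ligand then translates as a rigid body
#' on a Gaussian random walk whose per-frame step SD is
#' `drift_s0 + drift_s1 * max(0, pk_mid - label)`, so low-affinity
#' ligands wander further; pocket atoms get small iid jitter.
#'
#' @param crystal A labeled [complex_frame()] from [generate_complex()].
#' @param spec A [synthetic_spec()].
#' @param replicate_id Replicate index (drives the derived seed).
#' @return A [trajectory()] of `spec$n_frames` frames.
#' @export
generate_trajectory <- function(crystal, spec, replicate_id = 0L) {
  assert_that(is.finite(crystal$label_pk), "complex must carry a label")
  withr::with_seed(derive_seed(spec$seed, 2, crystal_index_of(crystal),
                               replicate_id), {
    t_len <- spec$n_frames
    atoms <- crystal$atoms
    n <- nrow(atoms)
    is_lig <- atoms$role == "ligand"
    base <- as.matrix(atoms[, c("x", "y", "z")])
    sigma <- spec$drift_s0 +
      spec$drift_s1 * max(0, spec$pk_mid - crystal$label_pk)
    coords <- array(0, c(t_len, n, 3))
    coords[1, , ] <- base
    drift <- c(0, 0, 0)
    if (t_len > 1) {
      for (t in 2:t_len) {
        drift <- drift + rnorm(3, 0, sigma)
        fr <- base
        fr[is_lig, ] <- sweep(fr[is_lig, , drop = FALSE], 2, drift, "+")
        if (spec$pocket_jitter_A > 0) {
          fr[!is_lig, ] <- fr[!is_lig, , drop = FALSE] +
            matrix(rnorm(sum(!is_lig) * 3, 0, spec$pocket_jitter_A),
                   sum(!is_lig), 3)
        }
        coords[t, , ] <- fr
      }
    }
    trajectory(atoms, coords, crystal$complex_id, replicate_id,
               crystal$label_pk)
  })
}

crystal_index_of <- function(crystal) {
  as.integer(sub("^syn", "", crystal$complex_id))
}

#' Generate a complete synthetic dataset in memory
#'
#' Complexes, replicate trajectories, and a manifest with complex-level
#' train/val/test splits and synthetic family/cluster labels.
#'
#' @param spec A [synthetic_spec()].
#' @return An [md_dataset()].
#' @export
generate_synthetic_set <- function(spec) {
  crystals <- purrr::map(seq_len(spec$n_complexes),
                         function(i) generate_complex(spec, i))
  names(crystals) <- vapply(crystals, function(f) f$complex_id, character(1))
  trajectories <- purrr::map(crystals, function(cr) {
    purrr::map(seq_len(spec$n_replicates) - 1L, function(r)
      generate_trajectory(cr, spec, r))
  })
  ids <- names(crystals)
  splits <- make_splits(ids, val_fraction = spec$val_fraction,
                        test_fraction = spec$test_fraction,
                        seed = derive_seed(spec$seed, 3))
  man <- manifest(
    complex_id = ids,
    label_pk = vapply(crystals, function(f) f$label_pk, numeric(1)),
    split = splits$split[match(ids, splits$complex_id)],
    protein_family = paste0("fam", (seq_along(ids) - 1L) %% 6L + 1L),
    cluster_id = paste0("cl", ceiling(seq_along(ids) / 5))
  )
  md_dataset(crystals, trajectories, man)
}

#' Write a synthetic dataset to disk
#'
#' Emits one crystal PDB (ligand residue `LIG`) and one annotation CSV
#' per complex, one trajectory container per replicate, and the manifest
#' CSV. On any failure the partially written output directory is
#' removed.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created; must not exist or be
#'   empty).
#' @return The [md_dataset()] that was written, invisibly.
#' @export
generate_dataset <- function(spec, out_dir) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0) {
    abort(sprintf("output directory '%s' is not empty", out_dir))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out_dir, recursive = TRUE))
  for (sub in c("structures", "annotations", "trajectories")) {
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)
  }
  ds <- generate_synthetic_set(spec)
  for (id in names(ds$crystals)) {
    write_complex_pdb(ds$crystals[[id]],
                      file.path(out_dir, "structures", paste0(id, ".pdb")))
    write_annotations(ds$crystals[[id]],
                      file.path(out_dir, "annotations", paste0(id, ".csv")))
    for (tr in ds$trajectories[[id]]) {
      write_trajectory(tr, file.path(out_dir, "trajectories",
                                     sprintf("%s_rep%02d.traj", id,
                                             tr$replicate_id)))
    }
  }
  write_manifest(ds$manifest, file.path(out_dir, "manifest.csv"))
  ok <- TRUE
  invisible(ds)
}

#' Write a complex frame as a PDB file
#'
#' Protein atoms become ATOM records; ligand atoms become HETATM records
#' of residue `LIG`.
#'
#' @param frame A [complex_frame()].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(frame, path) {
  a <- frame$atoms
  is_lig <- a$role == "ligand"
  resno <- integer(nrow(a))
  resid <- character(nrow(a))
  resid[is_lig] <- "LIG"
  resno[is_lig] <- 999L
  prot_res <- a$residue_id[!is_lig]
  resno[!is_lig] <- as.integer(factor(prot_res, levels = unique(prot_res)))
  resid[!is_lig] <- "GLY"
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(is_lig, "HETATM", "ATOM"),
    resno = resno, resid = resid,
    eleno = seq_len(nrow(a)),
    elety = make.unique(a$element, sep = ""),
    chain = rep("A", nrow(a)),
    elesy = a$element
  )
  invisible(path)
}

write_annotations <- function(frame, path) {
  a <- frame$atoms
  readr::write_csv(dplyr::bind_cols(
    tibble::tibble(eleno = seq_len(nrow(a))),
    a[, c("partial_charge", "hybridization", "heavy_valence",
          "hetero_valence", "is_hydrophobic", "is_aromatic", "is_acceptor",
          "is_donor", "is_ring")]
  ), path)
  invisible(path)
}

#' Load a dataset directory written by [generate_dataset()]
#'
#' @param dir Dataset directory containing `manifest.csv`,
#'   `structures/`, `annotations/` and `trajectories/`.
#' @return An [md_dataset()].
#' @export
load_dataset <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.csv"))
  crystals <- purrr::map(man$complex_id, function(id) {
    ann <- file.path(dir, "annotations", paste0(id, ".csv"))
    read_complex(file.path(dir, "structures", paste0(id, ".pdb")),
                 annotation_path = if (file.exists(ann)) ann else NULL,
                 ligand_resname = "LIG", complex_id = id,
                 label_pk = man$label_pk[man$complex_id == id])
  })
  names(crystals) <- man$complex_id
  traj_files <- list.files(file.path(dir, "trajectories"), full.names = TRUE)
  trajectories <- purrr::map(man$complex_id, function(id) {
    mine <- traj_files[grepl(paste0("^", id, "_rep"), basename(traj_files))]
    purrr::map(sort(mine), read_trajectory)
  })
  names(trajectories) <- man$complex_id
  md_dataset(crystals, trajectories, man)
}
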