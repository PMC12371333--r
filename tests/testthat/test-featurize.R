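# Pocket extraction, the 19-channel encoding, voxelization, rotations
# and partner ablation.

test_that("pocket selection is inclusive at the cutoff and matches brute force", {
  # residues with nearest atoms at 5, 11.9, 12.0 and 12.1 A from the
  # ligand center (single-atom ligand at the origin)
  prot <- rbind(c(5, 0, 0), c(0, 11.9, 0), c(0, 0, 12), c(12.1, 0, 0))
  fr <- toy_frame(prot, matrix(0, 1, 3),
                  protein_res = c("A:R1", "A:R2", "A:R3", "A:R4"))
  expect_equal(extract_pocket(fr, 12), c("A:R1", "A:R2", "A:R3"))
  expect_equal(extract_pocket(fr, 0), character(0))

  # randomized instances against an all-pairs scan
  for (i in 1:20) {
    set.seed(i)
    fr <- random_frame(n_prot = 60, n_lig = 5, radius = 15)
    got <- extract_pocket(fr, 12)
    lig <- fr$atoms[fr$atoms$role == "ligand", ]
    center <- c(mean(lig$x), mean(lig$y), mean(lig$z))
    prot <- fr$atoms[fr$atoms$role == "protein", ]
    d <- sqrt((prot$x - center[1])^2 + (prot$y - center[2])^2 +
                (prot$z - center[3])^2)
    want <- sort(unique(prot$residue_id[d <= 12]))
    expect_equal(got, want)
  }
})

test_that("single-atom ligand centers the pocket sphere on that atom", {
  fr <- toy_frame(rbind(c(3, 0, 0)), rbind(c(10, 10, 10)))
  expect_equal(ligand_center(fr), c(10, 10, 10))
  expect_error(extract_pocket(toy_frame(rbind(c(0, 0, 0)),
                                        matrix(0, 0, 3))), "no ligand")
})

test_that("encode_atoms lays out the 19 channels as documented", {
  expect_length(feature_channels(), 19)
  lig_c <- atom_table("C", 0, 0, 0, partial_charge = -0.1, hybridization = 3,
                      heavy_valence = 4, hetero_valence = 0,
                      is_hydrophobic = TRUE, is_ring = TRUE, role = "ligand")
  v <- encode_atoms(lig_c)[1, ]
  expect_equal(unname(v[1:9]), c(0, 1, 0, 0, 0, 0, 0, 0, 0))  # C one-hot
  expect_equal(unname(v[c("hybridization", "heavy_valence", "hetero_valence")]),
               c(3, 4, 0))
  expect_equal(unname(v[c("hydrophobic", "aromatic", "acceptor", "donor", "ring")]),
               c(1, 0, 0, 0, 1))
  expect_equal(unname(v["partial_charge"]), -0.1)
  expect_equal(unname(v["moltype"]), -1)

  prot_n <- atom_table("N", 0, 0, 0, is_aromatic = TRUE, is_acceptor = TRUE,
                       role = "protein")
  v2 <- encode_atoms(prot_n)[1, ]
  expect_equal(unname(v2["type_N"]), 1)
  expect_equal(sum(v2[1:9]), 1)
  expect_equal(unname(v2[c("aromatic", "acceptor", "moltype")]), c(1, 1, 1))

  zn <- encode_atoms(atom_table("Zn", 0, 0, 0))[1, ]
  expect_equal(unname(zn["type_metal"]), 1)
  expect_equal(sum(zn[1:9]), 1)
  halo <- encode_atoms(atom_table(c("F", "Cl", "Br", "I"), 1:4, 0, 0))
  expect_equal(unname(halo[, "type_halogen"]), rep(1, 4))
})

test_that("make_box maps atoms to half-open voxel cells and sums collisions", {
  # single atom exactly at the box center of a 25^3 grid -> voxel (13,13,13)
  fr <- toy_frame(matrix(0, 0, 3), rbind(c(0, 0, 0)))
  g <- make_box(fr, "pocket", edge_A = 25, resolution_A = 1)
  occupied <- which(apply(g$values != 0, 2:4, any), arr.ind = TRUE)
  expect_equal(unname(occupied[1, ]), c(13, 13, 13))  # 0-based (12,12,12)
  expect_equal(g$values[, 13, 13, 13], unname(encode_atoms(fr$atoms)[1, ]))

  # atom 13 A off-center is outside the box entirely
  fr_out <- toy_frame(rbind(c(13, 0, 0)), rbind(c(0, 0, 0)))
  g_out <- make_box(fr_out, "pocket", edge_A = 25, resolution_A = 1,
                    center = c(0, 0, 0))
  expect_equal(sum(apply(g_out$values != 0, 2:4, any)), 1)  # only the ligand

  # two identical atoms in one voxel double that voxel's channels
  at2 <- dplyr::bind_rows(atom_table("C", 0.2, 0.2, 0.2, role = "ligand"),
                          atom_table("C", 0.2, 0.2, 0.2, role = "ligand"))
  g2 <- make_box(complex_frame(at2, "c"), "pocket", edge_A = 10,
                 resolution_A = 1, center = c(0, 0, 0))
  one <- encode_atoms(at2[1, ])[1, ]
  expect_equal(g2$values[, 6, 6, 6], unname(2 * one))
  expect_error(make_box(fr, "pocket", edge_A = 25, resolution_A = 0.7),
               "not divisible")
})

test_that("grid mass is conserved channel by channel over in-box atoms", {
  for (i in 1:25) {
    set.seed(100 + i)
    fr <- random_frame(n_prot = 40, n_lig = 8, radius = 9)
    g <- make_box(fr, "pocket", edge_A = 20, resolution_A = 2)
    coords <- as.matrix(fr$atoms[, c("x", "y", "z")])
    idx <- floor(sweep(coords, 2, g$origin) / g$resolution_A)
    inside <- rowSums(idx >= 0 & idx < 10) == 3
    want <- colSums(encode_atoms(fr$atoms)[inside, , drop = FALSE])
    expect_equal(apply(g$values, 1, sum), unname(want), tolerance = 1e-12)
  }
})

test_that("the 24 right-angle rotations form the proper octahedral group", {
  rots <- enumerate_rotations()
  expect_length(rots, 24)
  mats <- purrr::map(rots, "mat")
  expect_equal(mats[[1]], diag(3))
  keys <- vapply(mats, function(m) paste(round(m), collapse = ","), character(1))
  expect_length(unique(keys), 24)
  for (m in mats) {
    expect_equal(crossprod(m), diag(3), tolerance = 1e-12)
    expect_equal(det(m), 1, tolerance = 1e-12)
  }
  # closure under composition
  for (i in seq(1, 24, 5)) for (j in seq(2, 24, 7)) {
    comp <- paste(round(mats[[i]] %*% mats[[j]]), collapse = ",")
    expect_true(comp %in% keys)
  }
})

test_that("apply_rotation is an isometry about the pivot", {
  fr <- toy_frame(rbind(c(1, 0, 0), c(0, 2, 0)), rbind(c(0, 0, 1)))
  id <- rotation(diag(3), tag = 0)
  expect_equal(frame_coords(apply_rotation(fr, id, c(1, 2, 3))),
               frame_coords(fr))
  rz <- rotation(matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3), tag = "z90")
  got <- frame_coords(apply_rotation(fr, rz, c(0, 0, 0)))
  expect_equal(unname(got[1, ]), c(0, 1, 0), tolerance = 1e-12)

  set.seed(5)
  fr2 <- random_frame()
  rot <- random_rotation("so3")
  center <- ligand_center(fr2)
  rotated <- apply_rotation(fr2, rot, center)
  d0 <- sqrt(rowSums(sweep(frame_coords(fr2), 2, center)^2))
  d1 <- sqrt(rowSums(sweep(frame_coords(rotated), 2,
                           ligand_center(rotated))^2))
  expect_equal(d0, d1, tolerance = 1e-9)
  expect_error(apply_rotation(fr2, matrix(1:9, 3)), "orthonormal")
})

test_that("voxelization is exactly equivariant under right-angle rotations", {
  rots <- enumerate_rotations()
  for (i in 1:10) {
    set.seed(200 + i)
    fr <- random_frame(n_prot = 30, n_lig = 6, radius = 8)
    center <- ligand_center(fr)
    g <- make_box(fr, "pocket", edge_A = 20, resolution_A = 2, center = center)
    rot <- rots[[sample.int(24, 1)]]
    g_rot_frame <- make_box(apply_rotation(fr, rot, center), "pocket",
                            edge_A = 20, resolution_A = 2, center = center)
    expect_identical(rotate_grid(g, rot)$values, g_rot_frame$values)
  }
})

test_that("partner ablation splits the grid additively and masks atoms", {
  set.seed(9)
  fr <- random_frame(n_prot = 20, n_lig = 5, radius = 7)
  expect_identical(mask_partner(fr, "complex"), fr)
  lig_only <- mask_partner(fr, "ligand_only")
  expect_equal(nrow(lig_only$atoms), 5)
  prot_only <- mask_partner(fr, "protein_only")
  expect_equal(nrow(prot_only$atoms), 20)
  center <- ligand_center(fr)
  g_all <- make_box(fr, "pocket", 20, 2, center = center)
  g_p <- make_box(prot_only, "pocket", 20, 2, center = center)
  g_l <- make_box(lig_only, "pocket", 20, 2, center = center)
  expect_equal(g_all$values, g_p$values + g_l$values, tolerance = 1e-12)
  empty <- mask_partner(fr, "ligand_only")
  expect_error(mask_partner(empty, "protein_only"), "no atoms")
})

test_that("pocket mode fixes the box while tracking mode follows the ligand", {
  ds <- tiny_synthetic()
  tr <- ds$trajectories[[1]][[1]]

  # rigid trajectory: every grid identical
  rigid <- trajectory(tr$atoms,
                      array(rep(tr$coords[1, , ], each = n_frames(tr)),
                            dim(tr$coords)),
                      tr$complex_id, 0L, tr$label_pk)
  vs <- voxelize_trajectory(rigid, "pocket", edge_A = 10, resolution_A = 2)
  for (t in 2:n_frames(rigid)) {
    expect_identical(vs$values[t, , , , ], vs$values[1, , , , ])
  }

  # uniform ligand translation with rigid internal geometry: tracking
  # recenters so ligand channels stay identical; pocket mode shifts them
  shift <- c(2.1, 0, 0)
  coords <- rigid$coords
  is_lig <- rigid$atoms$role == "ligand"
  for (t in seq_len(dim(coords)[1])) {
    coords[t, is_lig, ] <- sweep(coords[t, is_lig, , drop = FALSE][1, , ],
                                 2, (t - 1) * shift, "+")
  }
  lig_traj <- trajectory(rigid$atoms[is_lig, ],
                         coords[, is_lig, , drop = FALSE], "mv", 0L,
                         rigid$label_pk)
  vt <- voxelize_trajectory(lig_traj, "ligand_tracking", edge_A = 10,
                            resolution_A = 2)
  vp <- voxelize_trajectory(lig_traj, "pocket", edge_A = 10, resolution_A = 2)
  for (t in 2:n_frames(lig_traj)) {
    expect_identical(vt$values[t, , , , ], vt$values[1, , , , ])
  }
  expect_false(identical(vp$values[2, , , , ], vp$values[1, , , , ]))
})
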