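# Domain types, structure/trajectory readers, grid-dataset containers,
# manifest handling.

test_that("read_complex parses a toy PDB, assigns roles and drops hydrogens", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines(), pdb)
  fr <- read_complex(pdb)
  expect_s3_class(fr, "complex_frame")
  expect_equal(nrow(fr$atoms), 3)
  expect_equal(fr$atoms$role, c("protein", "protein", "ligand"))
  expect_equal(fr$replicate_id, -1L)

  pdb_h <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines(with_hydrogens = TRUE), pdb_h)
  fr_h <- read_complex(pdb_h)
  expect_equal(nrow(fr_h$atoms), 3)
  expect_false(any(fr_h$atoms$element == "H"))
})

test_that("read_complex errors when no ligand atoms can be identified", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "END"), pdb)
  expect_error(read_complex(pdb), "no ligand atoms")
})

test_that("annotation sidecars override the fallback annotator", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines(), pdb)
  ann <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    eleno = 1:3, partial_charge = c(-0.3, 0.1, 0.2),
    hybridization = c(2L, 3L, 3L), heavy_valence = c(3L, 2L, 1L),
    hetero_valence = c(1L, 0L, 0L), is_hydrophobic = c(FALSE, TRUE, FALSE),
    is_aromatic = c(TRUE, FALSE, FALSE), is_acceptor = c(FALSE, FALSE, TRUE),
    is_donor = FALSE, is_ring = c(TRUE, FALSE, FALSE)), ann)
  fr <- read_complex(pdb, annotation_path = ann)
  expect_equal(fr$atoms$partial_charge, c(-0.3, 0.1, 0.2))
  expect_equal(fr$atoms$hybridization, c(2L, 3L, 3L))
  expect_true(fr$atoms$is_aromatic[1])
})

test_that("multi-model PDB becomes a trajectory with one frame per model", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  body <- toy_pdb_lines()[1:3]
  writeLines(c("MODEL        1", body, "ENDMDL",
               "MODEL        2", sub("1\\.000", "1.500", body), "ENDMDL",
               "END"), pdb)
  tr <- read_trajectory(pdb)
  expect_s3_class(tr, "trajectory")
  expect_equal(n_frames(tr), 2)
  expect_equal(nrow(tr$atoms), 3)
  expect_equal(tr$frame_index, 0:1)
  expect_equal(tr$coords[2, 1, 1], 1.5)
})

test_that("trajectory constructor enforces the coordinate shape contract", {
  at <- atom_table(c("C", "C"), c(0, 1), c(0, 0), c(0, 0),
                   role = c("protein", "ligand"))
  coords <- array(0, c(50, 2, 3))
  tr <- trajectory(at, coords, "c1")
  expect_equal(n_frames(tr), 50)
  expect_error(trajectory(at, array(0, c(50, 2, 2)), "c1"),
               "3-dimensional")
  expect_error(trajectory(at, array(0, c(50, 3, 3)), "c1"), "3 atoms")
  expect_error(trajectory(at, coords, "c1", frame_index = c(5:1, 6:50)),
               "strictly increasing")
})

test_that("trajectory containers round-trip exactly", {
  ds <- tiny_synthetic()
  tr <- ds$trajectories[[1]][[1]]
  path <- withr::local_tempfile(fileext = ".traj")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$coords, tr$coords)
  expect_equal(back$atoms, tr$atoms)
  expect_equal(back$complex_id, tr$complex_id)
  expect_equal(back$label_pk, tr$label_pk)
  expect_equal(back$frame_index, tr$frame_index)
})

test_that("grid datasets round-trip arrays and attributes exactly", {
  set.seed(42)
  frames <- list(a = random_frame(complex_id = "a"),
                 b = random_frame(complex_id = "b"))
  grids <- purrr::map(frames, make_box, centering = "pocket",
                      edge_A = 25, resolution_A = 1)
  grids$a$label_pk <- 5.5
  grids$b$label_pk <- 7.25
  path <- withr::local_tempfile(fileext = ".grids")
  write_grid_dataset(list(train = grids), path)
  back <- read_grid_dataset(path)
  expect_equal(dim(back$train$grids), c(2, 19, 25, 25, 25))
  expect_identical(back$train$grids[1, , , , ], grids$a$values)
  expect_identical(back$train$grids[2, , , , ], grids$b$values)
  expect_equal(back$train$labels, c(5.5, 7.25))
  expect_equal(back$train$complex_ids, c("a", "b"))
  expect_equal(attr(back, "edge_A"), 25)
  expect_equal(attr(back, "resolution_A"), 1)
  expect_equal(attr(back, "channels"), feature_channels())
})

test_that("reading a grid dataset checks channel names and attributes", {
  set.seed(7)
  g <- make_box(random_frame(), edge_A = 10, resolution_A = 1)
  path <- withr::local_tempfile(fileext = ".grids")
  write_grid_dataset(list(train = list(g)), path)
  expect_error(read_grid_dataset(path, channels = rev(feature_channels())),
               "channel mismatch")
  expect_error(read_grid_dataset(path, channels = feature_channels()[-1]),
               "channel mismatch")
  expect_error(read_array_container(withr::local_tempfile()), "no such file")
})

test_that("voxel-sequence datasets keep the (N, T, C, D, D, D) layout", {
  ds <- tiny_synthetic()
  vs <- voxelize_trajectory(ds$trajectories[[1]][[1]], "pocket",
                            edge_A = 10, resolution_A = 2)
  path <- withr::local_tempfile(fileext = ".grids")
  write_grid_dataset(list(test = list(s1 = vs)), path)
  back <- read_grid_dataset(path)
  expect_equal(dim(back$test$grids), c(1, 4, 19, 5, 5, 5))
  expect_identical(back$test$grids[1, , , , , ], vs$values)
})

test_that("manifest split integrity is enforced and splits partition ids", {
  m <- toy_manifest(10)
  expect_true(check_split_integrity(m))
  expect_setequal(unique(m$split), c("train", "val", "test"))
  dup <- dplyr::bind_rows(m, dplyr::mutate(m[1, ], split = "test"))
  expect_error(validate_manifest(dup), "duplicated")
  expect_error(manifest("c1", 5, "holdout"), "unknown split")
})

test_that("manifest and prediction CSVs round-trip with exact columns", {
  m <- toy_manifest(6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, path)
  expect_equal(read_manifest(path), m)
  p <- tibble::tibble(complex_id = c("a", "b"), replicate_id = c(0L, -1L),
                      frame_index = c(3L, -1L), model_replicate = 1L,
                      predicted_pk = c(5, 6.5))
  pp <- withr::local_tempfile(fileext = ".csv")
  write_predictions(p, pp)
  expect_equal(names(readr::read_csv(pp, show_col_types = FALSE)),
               c("complex_id", "replicate_id", "frame_index",
                 "model_replicate", "predicted_pk"))
  expect_equal(read_predictions(pp)$predicted_pk, c(5, 6.5))
})
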