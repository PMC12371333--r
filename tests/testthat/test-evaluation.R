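# Metrics, the per-cluster Spearman summary, bias gaps, ligand-RMSD
# stability and generalization splits.

test_that("metrics match their standard definitions and hand-checked values", {
  truth <- c(3, 5, 10)
  expect_equal(pearson_r(truth, truth), 1)
  expect_equal(rmse(truth, truth), 0)
  expect_equal(spearman_rho(truth, truth), 1)
  centered <- truth - mean(truth)
  expect_equal(pearson_r(-centered, centered), -1)

  pred <- c(1, 2, 3)
  expect_equal(spearman_rho(pred, truth), 1)     # monotone -> rho = 1
  # hand-computed Pearson and RMSE for (1,2,3) vs (3,5,10)
  expect_equal(pearson_r(pred, truth), 7 / sqrt(2 * 26), tolerance = 1e-12)
  expect_equal(rmse(pred, truth), sqrt((4 + 9 + 49) / 3), tolerance = 1e-12)
})

test_that("metrics agree with an independent textbook implementation", {
  textbook_pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  textbook_spearman <- function(a, b) textbook_pearson(rank(a), rank(b))
  set.seed(99)
  for (n in c(5, 50, 1000)) {
    a <- rnorm(n)
    b <- 0.5 * a + rnorm(n)
    expect_equal(pearson_r(a, b), textbook_pearson(a, b), tolerance = 1e-12)
    expect_equal(spearman_rho(a, b), textbook_spearman(a, b),
                 tolerance = 1e-12)
    # with ties (average-tie ranks)
    bt <- round(b)
    expect_equal(spearman_rho(a, bt), textbook_spearman(a, bt),
                 tolerance = 1e-12)
  }
})

test_that("zero-variance inputs flag correlations as missing, never zero", {
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))
  expect_true(is.na(spearman_rho(c(2, 2), c(1, 3))))
  expect_equal(rmse(c(1, 1), c(1, 3)), sqrt(2))
})

test_that("per-cluster Spearman averages clusters and excludes singletons", {
  man <- manifest(sprintf("c%d", 1:7), label_pk = c(1, 2, 3, 4, 5, 6, 9),
                  split = "test",
                  cluster_id = c("A", "A", "A", "B", "B", "B", "S"))
  # cluster A perfectly ranked, cluster B perfectly inverted, S singleton
  preds <- tibble::tibble(
    complex_id = man$complex_id,
    predicted_pk = c(1.1, 2.2, 3.3, 6, 5, 4, 2))
  out <- spearman_per_cluster(preds, man)
  expect_equal(out$mean, 0)   # (1 + -1) / 2
  expect_true(out$table$excluded[out$table$cluster_id == "S"])
  expect_equal(sum(!out$table$excluded), 2)

  perfect <- tibble::tibble(complex_id = man$complex_id,
                            predicted_pk = man$label_pk + 0.1)
  expect_equal(spearman_per_cluster(perfect, man)$mean, 1)

  singletons <- manifest(c("x", "y"), c(1, 2), "test",
                         cluster_id = c("c1", "c2"))
  expect_error(spearman_per_cluster(
    tibble::tibble(complex_id = c("x", "y"), predicted_pk = c(1, 2)),
    singletons), "singleton")
})

test_that("compute_metrics assembles the full report", {
  man <- toy_manifest(9)
  preds <- tibble::tibble(complex_id = man$complex_id,
                          predicted_pk = man$label_pk + rnorm(9, 0, 0.1))
  rep_ <- compute_metrics(preds, man)
  expect_s3_class(rep_, "metrics_report")
  expect_equal(rep_$n_complexes, 9)
  expect_gt(rep_$pearson_r, 0.9)
  g <- glance(rep_)
  expect_named(g, c("pearson_r", "rmse_pk", "spearman_all",
                    "spearman_cluster_mean", "n_complexes"))
})

test_that("bias gap is the difference of replicate means and is antisymmetric", {
  expect_equal(bias_gap(c(0.9, 0.9), c(0.6, 0.6), "protein_only")$delta_r, 0.3)
  expect_equal(bias_gap(c(0.5, 0.7), c(0.5, 0.7), "ligand_only")$delta_r, 0)
  a <- c(0.8, 0.85, 0.9)
  b <- c(0.55, 0.6, 0.62)
  expect_equal(bias_gap(a, b, "ligand_only")$delta_r,
               -bias_gap(b, a, "ligand_only")$delta_r)
  expect_equal(bias_gap(a, b, "ligand_only")$n_model_replicates, 3)
})

test_that("ligand_max_rmsd is zero for rigid motion and exact for pure shifts", {
  ds <- tiny_synthetic()
  tr <- ds$trajectories[[1]][[1]]
  rigid <- trajectory(tr$atoms,
                      array(rep(tr$coords[1, , ], each = 4), c(4, nrow(tr$atoms), 3)),
                      "r", 0L, tr$label_pk)
  expect_equal(ligand_max_rmsd(rigid), 0)

  # ligand shifted by (3,0,0) in one frame, pocket fixed -> exactly 3
  coords <- rigid$coords
  is_lig <- rigid$atoms$role == "ligand"
  coords[3, is_lig, 1] <- coords[3, is_lig, 1] + 3
  shifted <- trajectory(rigid$atoms, coords, "s", 0L, tr$label_pk)
  expect_equal(ligand_max_rmsd(shifted), 3, tolerance = 1e-9)

  # whole-complex rigid rotation+translation of a frame is removed by
  # superposition
  rot <- random_rotation("so3")$mat
  coords2 <- rigid$coords
  moved <- coords2[2, , ] %*% t(rot)
  moved <- sweep(moved, 2, c(5, -3, 2), "+")
  coords2[2, , ] <- moved
  tumbled <- trajectory(rigid$atoms, coords2, "t", 0L, tr$label_pk)
  expect_lt(ligand_max_rmsd(tumbled), 1e-9)
})

test_that("superposition agrees with the bio3d reference fit", {
  set.seed(55)
  ref <- matrix(rnorm(30), 10, 3)
  rot <- random_rotation("so3")$mat
  mob <- sweep(ref %*% t(rot), 2, c(1, 2, 3), "+") +
    matrix(rnorm(30, 0, 0.05), 10, 3)
  fit <- mdaffinity:::kabsch_fit(ref, mob)
  ours <- mdaffinity:::apply_fit(mob, fit)
  b3d <- bio3d::fit.xyz(fixed = as.numeric(t(ref)),
                        mobile = as.numeric(t(mob)),
                        fixed.inds = 1:30, mobile.inds = 1:30)
  expect_equal(as.numeric(t(ours)), as.numeric(b3d), tolerance = 1e-6)
})

test_that("stability fractions behave at threshold extremes and split by affinity", {
  ds <- tiny_synthetic()
  tr <- ds$trajectories[[1]][[1]]
  rigid_traj <- function(id, pk) {
    trajectory(tr$atoms, array(rep(tr$coords[1, , ], each = 3),
                               c(3, nrow(tr$atoms), 3)), id, 0L, pk)
  }
  rigid_ds <- md_dataset(
    crystals = list(a = ds$crystals[[1]], b = ds$crystals[[2]]),
    trajectories = list(a = list(rigid_traj("a", 3)),
                        b = list(rigid_traj("b", 9))),
    manifest = manifest(c("a", "b"), c(3, 9), c("test", "test"))
  )
  st <- stability_fractions(rigid_ds, threshold_A = 2)
  expect_equal(st$fraction_stable_low, 1)
  expect_equal(st$fraction_stable_high, 1)
  st0 <- stability_fractions(ds, threshold_A = 0)
  expect_equal(st0$fraction_stable_low, 0)
  expect_equal(st0$fraction_stable_high, 0)
  # monotone non-decreasing in the threshold
  ths <- c(0.5, 1, 2, 4, 8)
  fr <- purrr::map_dbl(ths, function(th)
    mean(stability_fractions(ds, th)$per_complex$fraction_stable))
  expect_true(all(diff(fr) >= 0))
})

test_that("leave-family-out splits partition the manifest by family", {
  man <- toy_manifest(10)  # families alternate kinase/protease
  sp <- leave_family_out_split(man, "kinase")
  expect_equal(sp$n_test, 5)
  expect_equal(sp$n_train, 5)
  expect_true(all(sp$test$protein_family == "kinase"))
  expect_true(all(sp$train$protein_family != "kinase"))
  expect_setequal(c(sp$train$complex_id, sp$test$complex_id), man$complex_id)
  expect_error(leave_family_out_split(man, "gpcr"), "available")
})
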