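# Evaluation protocols: regression metrics (Pearson R, RMSE, Spearman
# rho overall and averaged over test-set clusters), the bias-gap
# comparison between full-complex and single-partner models, and the
# ligand-stability statistic (max ligand RMSD after pocket
# superposition).

#' Regression metrics on the pK scale
#'
#' Standard definitions; Spearman uses average-tie ranks. A zero-variance
#' input makes the correlations undefined: they are returned as `NA`
#' (flagged missing, never 0); RMSE is unaffected.
#'
#' @param pred,truth Paired numeric vectors (>= 2 finite pairs for the
#'   correlations).
#' @return `pearson_r()`, `spearman_rho()`: correlation in `[-1, 1]` or
#'   `NA`; `rmse()`: root mean square error in pK units.
#' @export
pearson_r <- function(pred, truth) {
  safe_cor(pred, truth, method = "pearson")
}

#' @rdname pearson_r
#' @export
spearman_rho <- function(pred, truth) {
  safe_cor(pred, truth, method = "spearman")
}

#' @rdname pearson_r
#' @export
rmse <- function(pred, truth) {
  assert_that(length(pred) == length(truth), "pred and truth lengths differ")
  sqrt(mean((pred - truth)^2))
}

safe_cor <- function(pred, truth, method) {
  assert_that(length(pred) == length(truth), "pred and truth lengths differ")
  if (length(pred) < 2 || sd(pred) == 0 || sd(truth) == 0) return(NA_real_)
  cor(pred, truth, method = method)
}

#' Per-cluster Spearman summary
#'
#' Computes Spearman's rho within each test-set cluster and reports
#' their unweighted mean over clusters with at least two members;
#' singleton clusters are excluded and flagged in the table.
#'
#' @param predictions Per-complex predictions tibble (`complex_id`,
#'   `predicted_pk`).
#' @param manifest Manifest with `cluster_id` populated.
#' @return List with `table` (cluster_id, n, spearman, excluded) and
#'   `mean` (unweighted mean over included clusters).
#' @export
spearman_per_cluster <- function(predictions, manifest) {
  manifest <- validate_manifest(manifest)
  joined <- dplyr::inner_join(predictions, manifest, by = "complex_id")
  assert_that(nrow(joined) > 0, "no predictions match the manifest")
  tab <- joined |>
    dplyr::group_by(cluster_id = .data$cluster_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      spearman = if (dplyr::n() >= 2)
        spearman_rho(.data$predicted_pk, .data$label_pk) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(excluded = .data$n < 2)
  assert_that(any(!tab$excluded), "all clusters are singletons")
  list(table = tab, mean = mean(tab$spearman[!tab$excluded]))
}

#' Full metrics report for per-complex predictions
#'
#' @param predictions Per-complex predictions (`complex_id`,
#'   `predicted_pk`), e.g. from [predict_per_complex()] or
#'   [consensus_predict()].
#' @param manifest Manifest tibble carrying `label_pk` (and optionally
#'   `cluster_id`).
#' @return A `metrics_report` with Pearson R, RMSE, Spearman overall,
#'   the per-cluster table and its mean, and the complex count.
#' @export
compute_metrics <- function(predictions, manifest) {
  manifest <- validate_manifest(manifest)
  joined <- dplyr::inner_join(predictions, manifest, by = "complex_id")
  assert_that(nrow(joined) > 0, "no predictions match the manifest")
  per_cluster <- if (!all(is.na(joined$cluster_id)) &&
                     any(table(joined$cluster_id) >= 2)) {
    spearman_per_cluster(predictions, manifest)
  } else {
    list(table = tibble::tibble(), mean = NA_real_)
  }
  structure(
    list(pearson_r = pearson_r(joined$predicted_pk, joined$label_pk),
         rmse_pk = rmse(joined$predicted_pk, joined$label_pk),
         spearman_all = spearman_rho(joined$predicted_pk, joined$label_pk),
         spearman_cluster_mean = per_cluster$mean,
         per_cluster = per_cluster$table,
         n_complexes = nrow(joined)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n=%d  R=%.3f  RMSE=%.3f pK  rho(all)=%.3f  rho(cluster mean)=%.3f\n",
    x$n_complexes, x$pearson_r, x$rmse_pk, x$spearman_all,
    x$spearman_cluster_mean))
  invisible(x)
}

#' @export
tidy.metrics_report <- function(x, ...) x$per_cluster

#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(pearson_r = x$pearson_r, rmse_pk = x$rmse_pk,
                 spearman_all = x$spearman_all,
                 spearman_cluster_mean = x$spearman_cluster_mean,
                 n_complexes = x$n_complexes)
}

#' Bias gap between full-complex and partner-ablated models
#'
#' The gap is the difference of mean test correlations across model
#' replicates: `delta_r = mean(R_complex) - mean(R_ablated)`. A large
#' positive gap means the models trained on the full complex genuinely
#' use interaction information that the ablated models cannot see.
#'
#' @param r_complex Per-replicate test Pearson R of full-complex models.
#' @param r_ablated Per-replicate test Pearson R of ablated models.
#' @param ablation Which partner was kept: `"protein_only"`,
#'   `"ligand_only"` or `"ligand_only_tracking"`.
#' @return A `bias_gap_report`.
#' @export
bias_gap <- function(r_complex, r_ablated,
                     ablation = c("protein_only", "ligand_only",
                                  "ligand_only_tracking")) {
  ablation <- match.arg(ablation)
  assert_that(length(r_complex) >= 1 && length(r_ablated) >= 1,
              "need at least one replicate per condition")
  structure(
    list(mean_r_complex = mean(r_complex),
         mean_r_ablated = mean(r_ablated),
         delta_r = mean(r_complex) - mean(r_ablated),
         ablation = ablation,
         n_model_replicates = length(r_complex)),
    class = "bias_gap_report"
  )
}

#' @export
print.bias_gap_report <- function(x, ...) {
  cat(sprintf("<bias_gap_report> %s: mean R %.3f (complex) vs %.3f (ablated), delta R = %.3f over %d replicates\n",
              x$ablation, x$mean_r_complex, x$mean_r_ablated, x$delta_r,
              x$n_model_replicates))
  invisible(x)
}

#' @export
glance.bias_gap_report <- function(x, ...) {
  tibble::tibble(ablation = x$ablation, mean_r_complex = x$mean_r_complex,
                 mean_r_ablated = x$mean_r_ablated, delta_r = x$delta_r,
                 n_model_replicates = x$n_model_replicates)
}

# rigid least-squares superposition (Kabsch) of mobile onto fixed
kabsch_fit <- function(fixed, mobile) {
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  h <- crossprod(sweep(mobile, 2, cm), sweep(fixed, 2, cf))
  sv <- svd(h)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rot = rot, shift_from = cm, shift_to = cf)
}

apply_fit <- function(coords, fit) {
  sweep(tcrossprod(sweep(coords, 2, fit$shift_from), fit$rot), 2,
        fit$shift_to, "+")
}

#' Maximum ligand RMSD over a trajectory
#'
#' Every frame is first rigidly superposed on the pocket heavy atoms of
#' the first frame (least-squares fit on protein atoms), which removes
#' global tumbling and isolates ligand motion relative to the binding
#' site. The RMSD of the ligand heavy atoms against the first frame is
#' then computed per frame and the maximum over the later frames
#' returned. A ligand is called stable when this maximum stays below a
#' threshold (2 Angstrom in the standard protocol).
#'
#' @param traj A [trajectory()] containing protein and ligand atoms.
#' @return Maximum ligand RMSD in Angstrom (0 for a 1-frame trajectory).
#' @export
ligand_max_rmsd <- function(traj) {
  is_lig <- traj$atoms$role == "ligand"
  assert_that(any(is_lig), "trajectory has no ligand atoms")
  assert_that(any(!is_lig), "trajectory has no pocket atoms to superpose on")
  t_len <- n_frames(traj)
  if (t_len < 2) return(0)
  ref <- traj$coords[1, , ]
  ref_pocket <- ref[!is_lig, , drop = FALSE]
  ref_lig <- ref[is_lig, , drop = FALSE]
  worst <- 0
  for (t in 2:t_len) {
    fr <- traj$coords[t, , ]
    fit <- kabsch_fit(ref_pocket, fr[!is_lig, , drop = FALSE])
    lig <- apply_fit(fr[is_lig, , drop = FALSE], fit)
    worst <- max(worst, sqrt(mean(rowSums((lig - ref_lig)^2))))
  }
  worst
}

#' Ligand stability fractions by affinity class
#'
#' A replicate simulation is stable when its maximum ligand RMSD
#' ([ligand_max_rmsd()]) stays below `threshold_A`; each complex's
#' stability is the fraction of its replicates that are stable, and the
#' report aggregates those per-complex fractions over the low- and
#' high-affinity classes (split at `affinity_split`, default the median
#' label).
#'
#' @param dataset An [md_dataset()] with labeled trajectories.
#' @param threshold_A Stability threshold in Angstrom (default 2).
#' @param affinity_split pK boundary between the classes; default median
#'   label of the complexes that have trajectories.
#' @return A `stability_report` with the per-complex table and the two
#'   class fractions (`NA` when a class is empty).
#' @export
stability_fractions <- function(dataset, threshold_A = 2,
                                affinity_split = NULL) {
  ids <- names(dataset$trajectories)
  ids <- ids[vapply(ids, function(id)
    length(dataset$trajectories[[id]]) > 0, logical(1))]
  assert_that(length(ids) > 0, "dataset has no trajectories")
  man <- dataset$manifest
  per_complex <- purrr::map_dfr(ids, function(id) {
    rmsds <- vapply(dataset$trajectories[[id]], ligand_max_rmsd, numeric(1))
    tibble::tibble(
      complex_id = id,
      label_pk = man$label_pk[match(id, man$complex_id)],
      n_replicates = length(rmsds),
      max_rmsd_mean = mean(rmsds),
      fraction_stable = mean(rmsds < threshold_A)
    )
  })
  affinity_split <- affinity_split %||% median(per_complex$label_pk)
  low <- per_complex$fraction_stable[per_complex$label_pk <= affinity_split]
  high <- per_complex$fraction_stable[per_complex$label_pk > affinity_split]
  structure(
    list(per_complex = per_complex, threshold_A = threshold_A,
         affinity_split = affinity_split,
         fraction_stable_low = if (length(low)) mean(low) else NA_real_,
         fraction_stable_high = if (length(high)) mean(high) else NA_real_),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> threshold %.1f A, split at pK %.2f: %.0f%% stable (low affinity) vs %.0f%% (high affinity)\n",
    x$threshold_A, x$affinity_split, 100 * x$fraction_stable_low,
    100 * x$fraction_stable_high))
  invisible(x)
}

#' @export
tidy.stability_report <- function(x, ...) x$per_complex

#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(threshold_A = x$threshold_A,
                 affinity_split = x$affinity_split,
                 fraction_stable_low = x$fraction_stable_low,
                 fraction_stable_high = x$fraction_stable_high,
                 n_complexes = nrow(x$per_complex))
}
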