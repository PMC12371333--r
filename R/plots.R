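# ggplot2 views of the result objects.

#' Scatter of predicted vs experimental affinity
#'
#' @param predictions Per-complex predictions (`complex_id`,
#'   `predicted_pk`).
#' @param manifest Manifest tibble with `label_pk`.
#' @return A ggplot object.
#' @export
plot_predictions <- function(predictions, manifest) {
  joined <- dplyr::inner_join(predictions, validate_manifest(manifest),
                              by = "complex_id")
  r <- pearson_r(joined$predicted_pk, joined$label_pk)
  e <- rmse(joined$predicted_pk, joined$label_pk)
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$label_pk,
                                       y = .data$predicted_pk)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "experimental pK", y = "predicted pK",
      title = sprintf("R = %.2f, RMSE = %.2f pK (n = %d)", r, e, nrow(joined))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.affinity_model <- function(object, ...) {
  assert_that(!is.null(object$history), "model has no training history")
  object$history |>
    tidyr::pivot_longer(c("train_mse", "val_rmse"), names_to = "metric") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trained_ensemble <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$val_rmse,
                                 group = .data$model_replicate)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "epoch", y = "validation RMSE (pK, per complex)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stability_report <- function(object, ...) {
  ggplot2::ggplot(object$per_complex,
                  ggplot2::aes(x = .data$label_pk, y = .data$max_rmsd_mean)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$threshold_A, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$affinity_split, linetype = 3) +
    ggplot2::labs(x = "affinity (pK)",
                  y = "mean over replicates of max ligand RMSD (A)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
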