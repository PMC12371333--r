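# The manifest is the experiment's table of record: one row per complex
# with its affinity label, split assignment, protein family and cluster.
# Every split operation is complex-exclusive: all frames and simulations
# of a complex live in exactly one of train/val/test.

#' Build and validate a dataset manifest
#'
#' @param complex_id Character vector of unique complex identifiers.
#' @param label_pk Affinity labels (pK units).
#' @param split One of `"train"`, `"val"`, `"test"` per complex.
#' @param protein_family,cluster_id Grouping labels used by the
#'   leave-family-out split and the per-cluster Spearman summary.
#' @return A validated manifest tibble.
#' @export
manifest <- function(complex_id, label_pk, split,
                     protein_family = NA_character_,
                     cluster_id = NA_character_) {
  validate_manifest(tibble::tibble(
    complex_id = as.character(complex_id),
    label_pk = as.numeric(label_pk),
    split = as.character(split),
    protein_family = as.character(protein_family),
    cluster_id = as.character(cluster_id)
  ))
}

#' Validate a manifest tibble
#'
#' Checks id uniqueness and that every complex sits in exactly one of
#' the three splits; this is the guard that makes data leakage across
#' the train/validation boundary impossible.
#'
#' @param m Manifest tibble.
#' @return `m`, invisibly validated (errors on violation).
#' @export
validate_manifest <- function(m) {
  need <- c("complex_id", "label_pk", "split")
  missing <- setdiff(need, names(m))
  assert_that(length(missing) == 0,
              paste("manifest missing columns:", paste(missing, collapse = ", ")))
  dup <- m$complex_id[duplicated(m$complex_id)]
  assert_that(length(dup) == 0,
              paste("duplicated complex_id in manifest:",
                    paste(unique(dup), collapse = ", ")))
  bad <- setdiff(unique(m$split), c("train", "val", "test"))
  assert_that(length(bad) == 0,
              paste("unknown split labels:", paste(bad, collapse = ", ")))
  if (!"protein_family" %in% names(m)) m$protein_family <- NA_character_
  if (!"cluster_id" %in% names(m)) m$cluster_id <- NA_character_
  m
}

#' Check split integrity of a manifest
#'
#' @param m Manifest tibble.
#' @return `TRUE` invisibly; errors if any complex appears in more than
#'   one split.
#' @export
check_split_integrity <- function(m) {
  m <- validate_manifest(m)
  per_split <- split(m$complex_id, m$split)
  ids <- unlist(per_split)
  assert_that(!any(duplicated(ids)),
              "split integrity violated: a complex appears in more than one split")
  invisible(TRUE)
}

#' Assign complex-level train/val(/test) splits
#'
#' Shuffles complexes with the given seed and assigns an 80/20
#' train/validation split (optionally reserving a test fraction first).
#' The assignment is at the complex level, never the frame level.
#'
#' @param complex_id Character vector of ids.
#' @param val_fraction Fraction of non-test complexes going to `val`
#'   (default 0.2).
#' @param test_fraction Fraction reserved as `test` (default 0).
#' @param seed Integer seed for the shuffle.
#' @return Tibble with `complex_id` and `split`.
#' @export
make_splits <- function(complex_id, val_fraction = 0.2, test_fraction = 0,
                        seed = 1L) {
  n <- length(complex_id)
  ord <- withr::with_seed(seed, sample.int(n))
  n_test <- round(n * test_fraction)
  n_val <- round((n - n_test) * val_fraction)
  split <- rep("train", n)
  split[ord[seq_len(n_test)]] <- "test"
  split[ord[n_test + seq_len(n_val)]] <- "val"
  tibble::tibble(complex_id = complex_id, split = split)
}

#' Leave-one-protein-family-out split
#'
#' Moves every complex of the named family into the test split and keeps
#' all remaining complexes for training; probes generalization to unseen
#' targets.
#'
#' @param m Manifest tibble with `protein_family` populated.
#' @param family Family name to hold out.
#' @return List with `train` and `test` manifest tibbles and the counts.
#' @export
leave_family_out_split <- function(m, family) {
  m <- validate_manifest(m)
  fams <- unique(m$protein_family)
  if (!family %in% fams) {
    abort(sprintf("unknown family '%s'; available: %s", family,
                  paste(sort(fams), collapse = ", ")))
  }
  test <- dplyr::filter(m, .data$protein_family == family) |>
    dplyr::mutate(split = "test")
  train <- dplyr::filter(m, .data$protein_family != family) |>
    dplyr::mutate(split = "train")
  list(train = train, test = test,
       n_train = nrow(train), n_test = nrow(test))
}

#' Read / write a manifest CSV
#'
#' @param path CSV path with header columns `complex_id`, `label_pk`,
#'   `split`, `protein_family`, `cluster_id`.
#' @return [read_manifest()]: validated manifest tibble.
#' @export
read_manifest <- function(path) {
  validate_manifest(readr::read_csv(path, show_col_types = FALSE,
                                    col_types = readr::cols(
                                      complex_id = readr::col_character()
                                    )))
}

#' @rdname read_manifest
#' @param m Manifest tibble.
#' @export
write_manifest <- function(m, path) {
  readr::write_csv(validate_manifest(m), path)
  invisible(path)
}

#' Read / write a predictions CSV
#'
#' Columns are exactly `complex_id`, `replicate_id`, `frame_index`,
#' `model_replicate`, `predicted_pk`; `frame_index` is `-1` for
#' whole-simulation predictions.
#'
#' @param path CSV path.
#' @return [read_predictions()]: predictions tibble.
#' @export
read_predictions <- function(path) {
  p <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(complex_id = readr::col_character()))
  validate_predictions(p)
}

#' @rdname read_predictions
#' @param p Predictions tibble.
#' @export
write_predictions <- function(p, path) {
  p <- validate_predictions(p)
  readr::write_csv(p[, c("complex_id", "replicate_id", "frame_index",
                         "model_replicate", "predicted_pk")], path)
  invisible(path)
}

validate_predictions <- function(p) {
  need <- c("complex_id", "replicate_id", "frame_index", "model_replicate",
            "predicted_pk")
  missing <- setdiff(need, names(p))
  assert_that(length(missing) == 0,
              paste("predictions missing columns:", paste(missing, collapse = ", ")))
  assert_that(all(is.finite(p$predicted_pk)), "predicted_pk must be finite")
  p
}
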