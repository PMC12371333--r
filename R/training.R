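# Training regimes.
#   crystal_only    - one sample per complex: the crystal-pose grid.
#   md_augmented    - the crystal grid plus every trajectory frame, each
#                     frame an independent sample carrying the parent
#                     complex's affinity label.
#   spatio_temporal - one whole-simulation voxel sequence per complex
#                     per epoch, the replicate drawn uniformly at random
#                     with the epoch RNG.
# Loss is mean squared error on the pK scale; the optimizer is Adam.
# During training one random rotation is drawn per sample per epoch; no
# rotation is applied at evaluation.

#' Training configuration
#'
#' @param regime `"crystal_only"`, `"md_augmented"` or
#'   `"spatio_temporal"`.
#' @param epochs Number of passes over the training split (>= 1).
#' @param batch_size Samples per optimizer step (>= 1).
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty added to gradients.
#' @param rotation Per-sample training rotation policy: `"random24"`
#'   (uniform over the 24 right-angle rotations, the default),
#'   `"random_so3"` (continuous uniform), or `"none"`.
#' @param patience Early-stopping patience in epochs on validation
#'   per-complex RMSE; `Inf` disables early stopping.
#' @param n_model_replicates Models per ensemble (default 10).
#' @param keep Partner mask applied to every frame
#'   ([mask_partner()]): `"complex"`, `"protein_only"`, `"ligand_only"`.
#' @param centering Box centering: `"pocket"` or `"ligand_tracking"`.
#' @param edge_A,resolution_A Voxelization geometry.
#' @param seed Base seed; replicate seeds are derived from it and
#'   recorded.
#' @return A `training_config` object.
#' @export
training_config <- function(regime = c("md_augmented", "crystal_only",
                                       "spatio_temporal"),
                            epochs = 30L, batch_size = 16L, lr = 1e-3,
                            weight_decay = 0,
                            rotation = c("random24", "random_so3", "none"),
                            patience = Inf, n_model_replicates = 10L,
                            keep = c("complex", "protein_only", "ligand_only"),
                            centering = c("pocket", "ligand_tracking"),
                            edge_A = 25, resolution_A = 1, seed = 1L) {
  regime <- match.arg(regime)
  rotation <- match.arg(rotation)
  keep <- match.arg(keep)
  centering <- match.arg(centering)
  assert_that(epochs >= 1, "epochs must be >= 1")
  assert_that(batch_size >= 1, "batch_size must be >= 1")
  structure(
    list(regime = regime, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), lr = lr,
         weight_decay = weight_decay, rotation = rotation,
         patience = as.numeric(patience),  # tolerate "Inf" from JSON configs

         n_model_replicates = as.integer(n_model_replicates),
         keep = keep, centering = centering, edge_A = edge_A,
         resolution_A = resolution_A, seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Bundle crystals, trajectories and a manifest into a dataset
#'
#' @param crystals Named list of crystal [complex_frame()]s, keyed by
#'   complex id.
#' @param trajectories Named list (keyed by complex id) of lists of
#'   [trajectory()] objects, one per replicate.
#' @param manifest Manifest tibble ([manifest()]).
#' @return An object of class `md_dataset`.
#' @export
md_dataset <- function(crystals, trajectories, manifest) {
  manifest <- validate_manifest(manifest)
  missing <- setdiff(manifest$complex_id, names(crystals))
  assert_that(length(missing) == 0,
              paste("manifest complexes without structures:",
                    paste(head(missing, 5), collapse = ", ")))
  structure(list(crystals = crystals, trajectories = trajectories,
                 manifest = manifest),
            class = "md_dataset")
}

#' @export
print.md_dataset <- function(x, ...) {
  n_traj <- sum(vapply(x$trajectories, length, numeric(1)))
  cat(sprintf("<md_dataset> %d complexes, %d trajectories (splits: %s)\n",
              nrow(x$manifest), n_traj,
              paste(sprintf("%s=%d", names(table(x$manifest$split)),
                            table(x$manifest$split)), collapse = ", ")))
  invisible(x)
}

#' Enumerate the samples of one training epoch
#'
#' `crystal_only` yields one crystal sample per complex; `md_augmented`
#' yields the crystal plus every trajectory frame, each labeled with the
#' complex's affinity; `spatio_temporal` yields exactly one
#' whole-simulation sample per complex, with the replicate drawn
#' uniformly at random using the epoch seed.
#'
#' @param dataset An [md_dataset()].
#' @param regime Training regime string.
#' @param split Which manifest split to enumerate (default `"train"`).
#' @param epoch_seed Seed for the per-epoch replicate draw
#'   (spatio_temporal only).
#' @return Tibble with columns `complex_id`, `replicate_id`,
#'   `frame_index` (`-1` for whole-simulation samples), `label_pk`.
#' @export
build_epoch_samples <- function(dataset, regime, split = "train",
                                epoch_seed = 1L) {
  man <- dataset$manifest[dataset$manifest$split == split, ]
  if (regime == "spatio_temporal") {
    missing <- man$complex_id[!vapply(man$complex_id, function(id)
      length(dataset$trajectories[[id]]) > 0, logical(1))]
    assert_that(length(missing) == 0,
                paste("complexes without trajectories in spatio_temporal regime:",
                      paste(missing, collapse = ", ")))
    picks <- withr::with_seed(epoch_seed, vapply(man$complex_id, function(id)
      sample.int(length(dataset$trajectories[[id]]), 1), integer(1)))
    return(tibble::tibble(
      complex_id = man$complex_id,
      replicate_id = vapply(seq_along(picks), function(i)
        dataset$trajectories[[man$complex_id[i]]][[picks[i]]]$replicate_id,
        integer(1)),
      frame_index = -1L,
      label_pk = man$label_pk
    ))
  }
  crystal <- tibble::tibble(complex_id = man$complex_id, replicate_id = -1L,
                            frame_index = 0L, label_pk = man$label_pk)
  if (regime == "crystal_only") return(crystal)
  frames <- purrr::map_dfr(man$complex_id, function(id) {
    trajs <- dataset$trajectories[[id]]
    if (length(trajs) == 0) return(NULL)
    purrr::map_dfr(trajs, function(tr) {
      tibble::tibble(complex_id = id, replicate_id = tr$replicate_id,
                     frame_index = tr$frame_index,
                     label_pk = man$label_pk[man$complex_id == id])
    })
  })
  dplyr::bind_rows(crystal, frames)
}

# precomputed per-complex featurization context (pocket selection and
# fixed box center are computed once on the crystal pose)
featurize_context <- function(dataset, tcfg, radius_A = 12) {
  ids <- dataset$manifest$complex_id
  ctx <- purrr::map(ids, function(id) {
    crystal <- dataset$crystals[[id]]
    list(pocket = extract_pocket(crystal, radius_A),
         center = ligand_center(crystal))
  })
  names(ctx) <- ids
  ctx
}

frame_for_sample <- function(dataset, id, replicate_id, frame_pos) {
  if (replicate_id == -1L) return(dataset$crystals[[id]])
  trajs <- dataset$trajectories[[id]]
  rep_ids <- vapply(trajs, function(t) t$replicate_id, integer(1))
  traj <- trajs[[which(rep_ids == replicate_id)]]
  traj_frame(traj, frame_pos)
}

prepare_frame <- function(frame, ctx, tcfg) {
  frame <- restrict_to_pocket(frame, ctx$pocket)
  frame <- mask_partner(frame, tcfg$keep)
  frame
}

sample_rotation <- function(tcfg) {
  switch(tcfg$rotation,
         none = NULL,
         random24 = random_rotation("right_angle"),
         random_so3 = random_rotation("so3"))
}

# voxelize a block of sample rows into a batch tensor
voxelize_samples <- function(dataset, rows, ctx, tcfg, rotate = FALSE) {
  sequencing <- tcfg$regime == "spatio_temporal"
  arrs <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    id <- rows$complex_id[i]
    cc <- ctx[[id]]
    rot <- if (rotate) sample_rotation(tcfg) else NULL
    if (sequencing) {
      trajs <- dataset$trajectories[[id]]
      rep_ids <- vapply(trajs, function(t) t$replicate_id, integer(1))
      traj <- trajs[[which(rep_ids == rows$replicate_id[i])]]
      traj <- mask_trajectory(traj, cc, tcfg)
      vs <- voxelize_trajectory(traj,
                                centering = tcfg$centering,
                                edge_A = tcfg$edge_A,
                                resolution_A = tcfg$resolution_A,
                                center = cc$center, rotation = rot,
                                pivot = cc$center)
      arrs[[i]] <- vs$values
    } else {
      fr <- frame_for_sample(dataset, id, rows$replicate_id[i],
                             rows$frame_pos[i])
      fr <- prepare_frame(fr, cc, tcfg)
      if (!is.null(rot)) fr <- apply_rotation(fr, rot, cc$center)
      g <- make_box(fr, centering = tcfg$centering, edge_A = tcfg$edge_A,
                    resolution_A = tcfg$resolution_A, center = cc$center)
      arrs[[i]] <- g$values
    }
  }
  dims <- dim(arrs[[1]])
  flat <- vapply(arrs, as.numeric, numeric(prod(dims)))
  array(flat, c(dims, length(arrs)))
}

# apply pocket restriction + partner mask to a whole trajectory
mask_trajectory <- function(traj, ctx, tcfg) {
  keep <- traj$atoms$role == "ligand" | traj$atoms$residue_id %in% ctx$pocket
  if (tcfg$keep == "protein_only") keep <- keep & traj$atoms$role == "protein"
  if (tcfg$keep == "ligand_only") keep <- keep & traj$atoms$role == "ligand"
  assert_that(any(keep), "mask leaves no atoms in trajectory")
  trajectory(traj$atoms[keep, ], traj$coords[, keep, , drop = FALSE],
             traj$complex_id, traj$replicate_id, traj$label_pk,
             traj$frame_index)
}

# attach a 1-based frame position (into the trajectory array) to sample
# rows; crystal samples get position 1
attach_frame_pos <- function(dataset, rows) {
  pos <- integer(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    if (rows$replicate_id[i] == -1L) {
      pos[i] <- 1L
    } else {
      trajs <- dataset$trajectories[[rows$complex_id[i]]]
      rep_ids <- vapply(trajs, function(t) t$replicate_id, integer(1))
      tr <- trajs[[which(rep_ids == rows$replicate_id[i])]]
      pos[i] <- which(tr$frame_index == rows$frame_index[i])
    }
  }
  rows$frame_pos <- pos
  rows
}

#' Train one affinity model
#'
#' Runs the configured regime: per-epoch sample enumeration, one random
#' rotation per sample, minibatch Adam on the MSE loss, per-complex
#' validation RMSE after every epoch, and best-checkpoint selection
#' (lowest validation RMSE). Train/validation splits are asserted
#' complex-disjoint before any optimization.
#'
#' @param dataset An [md_dataset()].
#' @param mcfg A [model_config()].
#' @param tcfg A [training_config()].
#' @param verbose Print per-epoch losses.
#' @return An `affinity_model` with a `history` tibble (epoch, train
#'   MSE, validation per-complex RMSE) and the seed recorded.
#' @export
train_affinity_model <- function(dataset, mcfg, tcfg, verbose = FALSE) {
  check_split_integrity(dataset$manifest)
  ctx <- featurize_context(dataset, tcfg)
  mcfg$seed <- tcfg$seed
  model <- affinity_model(mcfg)
  opt <- adam_init(model$params)
  history <- tibble::tibble(epoch = integer(), train_mse = numeric(),
                            val_rmse = numeric())
  best <- list(rmse = Inf, params = model$params)
  stall <- 0
  for (epoch in seq_len(tcfg$epochs)) {
    epoch_seed <- derive_seed(tcfg$seed, epoch)
    samples <- build_epoch_samples(dataset, tcfg$regime, "train", epoch_seed)
    if (tcfg$regime != "spatio_temporal") {
      samples <- attach_frame_pos(dataset, samples)
    }
    withr::with_seed(epoch_seed, {
      ord <- sample.int(nrow(samples))
      samples <- samples[ord, ]
      batch_losses <- numeric(0)
      for (start in seq(1, nrow(samples), tcfg$batch_size)) {
        rows <- samples[start:min(start + tcfg$batch_size - 1, nrow(samples)), ]
        x <- voxelize_samples(dataset, rows, ctx, tcfg,
                              rotate = tcfg$rotation != "none")
        y <- rows$label_pk
        fw <- model_forward(model, x, train = TRUE)
        pred <- as.numeric(fw$out)
        loss <- mean((pred - y)^2)
        dout <- matrix(2 * (pred - y) / length(y), 1)
        grads <- model_backward(model, fw, dout)
        grads <- grads[names(model$params)]
        step <- adam_step(model$params, grads, opt, lr = tcfg$lr,
                          weight_decay = tcfg$weight_decay)
        model$params <- step$params
        opt <- step$state
        batch_losses <- c(batch_losses, loss)
      }
    })
    val_rmse <- validation_rmse(model, dataset, ctx, tcfg)
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = epoch, train_mse = mean(batch_losses), val_rmse = val_rmse))
    if (verbose) {
      inform(sprintf("epoch %d  train mse %.4f  val rmse %.4f",
                     epoch, mean(batch_losses), val_rmse))
    }
    if (is.finite(val_rmse) && val_rmse < best$rmse) {
      best <- list(rmse = val_rmse, params = model$params)
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall > tcfg$patience) break
    }
  }
  model$params <- best$params
  model$history <- history
  model$seed <- tcfg$seed
  model$tcfg <- tcfg
  model
}

# per-complex validation RMSE: frames (or sequences) of the val split
# are predicted without rotation and averaged per complex
validation_rmse <- function(model, dataset, ctx, tcfg, split = "val") {
  man <- dataset$manifest[dataset$manifest$split == split, ]
  if (nrow(man) == 0) return(NA_real_)
  preds <- predict_entities(model, dataset, ctx, tcfg, split)
  agg <- predict_per_complex(preds)
  truth <- man$label_pk[match(agg$complex_id, man$complex_id)]
  sqrt(mean((agg$predicted_pk - truth)^2))
}

# entity-level predictions for a split: per frame for 3D families, per
# whole simulation for sequence families; crystal frames are used when a
# complex has no trajectories
predict_entities <- function(model, dataset, ctx, tcfg, split,
                             model_replicate = 1L, batch_size = 64L) {
  man <- dataset$manifest[dataset$manifest$split == split, ]
  sequencing <- model$config$family %in% c("lrcn", "convlstm")
  rows <- if (sequencing) {
    purrr::map_dfr(man$complex_id, function(id) {
      trajs <- dataset$trajectories[[id]]
      assert_that(length(trajs) > 0,
                  sprintf("complex '%s' has no trajectories to predict on", id))
      tibble::tibble(complex_id = id,
                     replicate_id = vapply(trajs, function(t) t$replicate_id,
                                           integer(1)),
                     frame_index = -1L)
    })
  } else {
    purrr::map_dfr(man$complex_id, function(id) {
      trajs <- dataset$trajectories[[id]]
      if (length(trajs) == 0) {
        return(tibble::tibble(complex_id = id, replicate_id = -1L,
                              frame_index = 0L))
      }
      purrr::map_dfr(trajs, function(tr) {
        tibble::tibble(complex_id = id, replicate_id = tr$replicate_id,
                       frame_index = tr$frame_index)
      })
    })
  }
  tcfg_eval <- tcfg
  tcfg_eval$regime <- if (sequencing) "spatio_temporal" else "md_augmented"
  if (!sequencing) rows <- attach_frame_pos(dataset, rows)
  preds <- numeric(nrow(rows))
  if (sequencing) batch_size <- max(1L, batch_size %/% 8L)
  for (start in seq(1, nrow(rows), batch_size)) {
    block <- rows[start:min(start + batch_size - 1, nrow(rows)), ]
    x <- voxelize_samples(dataset, block, ctx, tcfg_eval, rotate = FALSE)
    preds[start:(start + nrow(block) - 1)] <-
      as.numeric(model_forward(model, x, train = FALSE)$out)
  }
  tibble::tibble(complex_id = rows$complex_id,
                 replicate_id = rows$replicate_id,
                 frame_index = rows$frame_index,
                 model_replicate = as.integer(model_replicate),
                 predicted_pk = preds)
}

#' Predict a split of a dataset with one model
#'
#' Produces entity-level predictions (per frame for the 3D families, per
#' whole simulation for the sequence families) with full provenance.
#'
#' @param model A trained [affinity_model()].
#' @param dataset An [md_dataset()].
#' @param split Manifest split to predict (default `"test"`).
#' @param tcfg Optional [training_config()] carrying the featurization
#'   settings; defaults to the one stored on the model.
#' @param model_replicate Integer tag recorded in the output.
#' @return Predictions tibble (`complex_id`, `replicate_id`,
#'   `frame_index`, `model_replicate`, `predicted_pk`).
#' @export
predict_dataset <- function(model, dataset, split = "test", tcfg = NULL,
                            model_replicate = 1L) {
  tcfg <- tcfg %||% model$tcfg
  assert_that(!is.null(tcfg), "no training_config available for featurization")
  ctx <- featurize_context(dataset, tcfg)
  predict_entities(model, dataset, ctx, tcfg, split, model_replicate)
}

#' Aggregate entity-level predictions per complex
#'
#' The per-complex prediction is the arithmetic mean of the entity-level
#' predictions: over all frames of all replicate simulations for the 3D
#' families, or over the whole-simulation predictions for the sequence
#' families. With a balanced design (equal frames per replicate) this
#' equals the mean of per-replicate means.
#'
#' @param predictions Predictions tibble.
#' @return Tibble `complex_id`, `model_replicate`, `predicted_pk`,
#'   `n_entities`.
#' @export
predict_per_complex <- function(predictions) {
  validate_predictions(predictions)
  predictions |>
    dplyr::group_by(.data$complex_id, .data$model_replicate) |>
    dplyr::summarise(n_entities = dplyr::n(),
                     predicted_pk = mean(.data$predicted_pk),
                     .groups = "drop")
}

#' Train an ensemble of model replicates
#'
#' Trains `n_model_replicates` models that differ only in their seeds
#' (parameter initialization, rotation draws, batch order, replicate
#' draws); seeds are derived from the base seed and recorded per model.
#'
#' @inheritParams train_affinity_model
#' @return A `trained_ensemble`: list of models plus their histories.
#' @export
train_affinity_ensemble <- function(dataset, mcfg, tcfg, verbose = FALSE) {
  models <- vector("list", tcfg$n_model_replicates)
  for (r in seq_len(tcfg$n_model_replicates)) {
    tr <- tcfg
    tr$seed <- derive_seed(tcfg$seed, 1000 + r)
    models[[r]] <- train_affinity_model(dataset, mcfg, tr, verbose = verbose)
  }
  seeds <- vapply(models, function(m) m$seed, integer(1))
  assert_that(!any(duplicated(seeds)), "replicate seeds must be distinct")
  structure(list(models = models, seeds = seeds, tcfg = tcfg),
            class = "trained_ensemble")
}

#' @export
print.trained_ensemble <- function(x, ...) {
  cat(sprintf("<trained_ensemble> %d x %s models (best val RMSE %.3f-%.3f)\n",
              length(x$models), x$models[[1]]$config$family,
              min(vapply(x$models, function(m) min(m$history$val_rmse), numeric(1))),
              max(vapply(x$models, function(m) min(m$history$val_rmse), numeric(1)))))
  invisible(x)
}

#' Consensus prediction across model replicates
#'
#' The consensus per-complex prediction is the mean over model
#' replicates of the per-complex aggregated predictions.
#'
#' @param ensemble A [train_affinity_ensemble()] result, or a list of
#'   models.
#' @param dataset An [md_dataset()].
#' @param split Split to predict.
#' @return Tibble `complex_id`, `predicted_pk` (consensus), plus the
#'   per-replicate predictions in the attribute `"per_replicate"`.
#' @export
consensus_predict <- function(ensemble, dataset, split = "test") {
  models <- if (inherits(ensemble, "trained_ensemble")) ensemble$models else ensemble
  assert_that(length(models) >= 1, "need at least one model")
  per_rep <- purrr::imap_dfr(models, function(m, r) {
    predict_dataset(m, dataset, split, model_replicate = r) |>
      predict_per_complex()
  })
  out <- per_rep |>
    dplyr::group_by(.data$complex_id) |>
    dplyr::summarise(predicted_pk = mean(.data$predicted_pk), .groups = "drop")
  attr(out, "per_replicate") <- per_rep
  out
}

#' @export
tidy.affinity_model <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble())
  x$history
}

#' @export
glance.affinity_model <- function(x, ...) {
  tibble::tibble(
    family = x$config$family,
    n_parameters = n_parameters(x),
    epochs_run = if (is.null(x$history)) 0L else nrow(x$history),
    best_val_rmse = if (is.null(x$history)) NA_real_ else min(x$history$val_rmse),
    seed = x$seed %||% x$config$seed
  )
}

#' @export
tidy.trained_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$models, function(m, r) {
    dplyr::mutate(m$history, model_replicate = r, .before = 1)
  })
}

#' @export
glance.trained_ensemble <- function(x, ...) {
  tibble::tibble(
    family = x$models[[1]]$config$family,
    n_model_replicates = length(x$models),
    best_val_rmse = min(vapply(x$models, function(m) min(m$history$val_rmse),
                               numeric(1)))
  )
}
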