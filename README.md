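# mdaffinity

Predicting protein–ligand binding affinity from molecular-dynamics
trajectories in R.

Structure-based affinity models are usually trained on a single crystal
pose per complex. `mdaffinity` implements the trajectory-based
alternative: the binding pocket is voxelized into a cubic feature grid
frame by frame, and affinity (pK = −log10 of Kd/Ki) is regressed either
from individual MD frames used as extra training samples (*MD data
augmentation*) or from whole ordered frame sequences (*spatio-temporal
learning*). The package is aimed at method developers in structural
bioinformatics who want a complete, desk-scale, fully testable
implementation of this pipeline — featurization, models, training
regimes, and the evaluation protocols that probe what such models
actually learn.

## What's inside

- **Featurization.** Pocket residues are selected once on the crystal
  pose (every residue with a heavy atom within 12 Å of the ligand's
  geometric center). A cubic box (default 25 Å edge, 1 Å³ voxels) is
  centered on the ligand; every heavy atom contributes a 19-channel
  feature vector (9 one-hot atom types, hybridization, heavy/hetero
  valence, 5 pharmacophore flags, partial charge, molecule type ±1) to
  the voxel containing it. Rotation augmentation uses the 24 right-angle
  rotations of the cube (continuous rotations optional); ablation masks
  (protein-only / ligand-only) and a ligand-tracking box mode support
  the bias protocols.
- **Models.** Four families mapping grids or grid sequences to a pK
  scalar, implemented from scratch on BLAS: a plain 3D CNN; a
  dense-block CNN (each layer's input concatenated to its output,
  channels `in + layers × growth`, transitions compress by `floor(c·θ)`
  and pool by 2); an LRCN (shared per-frame CNN encoder feeding an LSTM);
  and a ConvLSTM (gates are 3D convolutions; `i,f,o = σ(·)`,
  `g = tanh(·)`, `c_t = f⊙c_{t−1} + i⊙g`, `h_t = o⊙tanh(c_t)`, no
  peepholes). Exact backpropagation and Adam are included; all forwards
  are verified against numerical gradients and analytic oracles.
- **Training regimes.** `crystal_only` (one grid per complex),
  `md_augmented` (crystal plus every trajectory frame, each labeled
  with the parent complex's affinity), and `spatio_temporal` (one whole
  simulation per complex per epoch, replicate drawn at random). Splits
  are complex-exclusive by construction, per-complex predictions are
  means over frames (or over whole-simulation predictions), and
  consensus averages over model replicates.
- **Evaluation.** Pearson R, RMSE, Spearman ρ overall and averaged per
  cluster; the bias gap ΔR = mean R(complex) − mean R(ablated); and the
  ligand-stability statistic: max ligand RMSD per replicate after
  superposing each frame on the pocket, with stability fractions by
  affinity class at a 2 Å threshold.
- **Synthetic data.** A generator of toy complexes (pocket shell +
  ligand) whose label is a known linear function of ligand–pocket
  contacts, with replicate trajectories whose ligand drift grows as
  affinity drops — so every claim above is testable end to end in
  minutes on one CPU.

## Worked example

```r
library(mdaffinity)

# a desk-scale synthetic corpus: 60 complexes, 2 replicate trajectories
# of 3 frames each, complex-exclusive train/val/test splits
ds <- generate_synthetic_set(
  synthetic_spec(n_complexes = 60, n_replicates = 2, n_frames = 3))

mcfg <- model_config("cnn", grid_edge = 8, conv_channels = c(12, 16, 32),
                     conv_kernel = c(1, 3, 3), head = c(64))
tcfg <- training_config("md_augmented", epochs = 15, batch_size = 16,
                        edge_A = 24, resolution_A = 3, seed = 11)
model <- train_affinity_model(ds, mcfg, tcfg, verbose = TRUE)
#> epoch 1  train mse 8.5438  val rmse 0.8497
#> epoch 2  train mse 2.3430  val rmse 1.7156
#> ...
#> epoch 15  train mse 0.7775  val rmse 1.0054

preds <- predict_dataset(model, ds, "test") |> predict_per_complex()
compute_metrics(preds, ds$manifest)
#> <metrics_report> n=12  R=0.947  RMSE=2.222 pK  rho(all)=0.965  rho(cluster mean)=1.000
```

The train MSE falls from ~9 (the label variance seen by an untrained
model) to below 1 pK²; the held-out per-complex Pearson R of ~0.95
shows the network has recovered the planted contact signal rather than
memorized frames — every frame of a test complex was unseen during
training. (The RMSE is larger than the correlation suggests because the
retained best-validation checkpoint here is an early epoch whose
predictions are still compressed toward the mean; correlation and
ranking, which the protocols focus on, are unaffected.)

Ligand stability follows the planted drift model:

```r
st <- stability_fractions(generate_synthetic_set(
  synthetic_spec(n_complexes = 40, n_replicates = 5)), threshold_A = 2)
st
#> <stability_report> threshold 2.0 A, split at pK 4.97: 41% stable (low affinity) vs 55% (high affinity)
```

A command-line interface wraps the same functions
(`inst/cli/mdaffinity.R`: `simulate`, `featurize`, `train`, `predict`,
`evaluate`, `stability`, `split`, `describe`).

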