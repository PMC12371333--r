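---
title: "Learning binding affinity from MD trajectories: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning binding affinity from MD trajectories: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mdaffinity)
```

## The problem and the approach

Binding affinity is reported as pK = −log10 of a dissociation or
inhibition constant; predicting it from structure is a regression task.
Most grid-based deep models see a single crystallographic pose per
complex. `mdaffinity` implements the trajectory-based extension of that
idea in three regimes:

* **crystal_only** — the classical baseline: one voxel grid per
  complex, built from the crystal pose.
* **md_augmented** — every frame of every replicate simulation becomes
  an independent training sample, labeled with the parent complex's
  affinity. The model still sees 3D inputs but learns from the
  conformational ensemble rather than one snapshot.
* **spatio_temporal** — the whole ordered frame sequence is a single 4D
  sample, so the model can exploit temporal structure such as how much
  the ligand wanders in the pocket. One replicate per complex is drawn
  per epoch (uniformly, with the epoch RNG), which trades gradient
  variance for a tractable epoch size.

## Featurization

The pocket is defined once, on the crystal pose: every protein residue
with at least one heavy atom within 12 Å (inclusive) of the geometric
center of the ligand's heavy atoms. The same residue selection and the
same box center are reused for all frames and replicates, so the frame
pipeline and the crystal pipeline are identical up to coordinates. Two
details the definition leaves open were fixed as follows: the distance
is measured center-to-any-heavy-atom (not to residue centroids), and
the boundary is inclusive, which makes the selection testable against a
brute-force all-pairs scan with no tolerance.

Voxelization places a cubic box (default edge 25 Å, voxels 1 Å³) around
the ligand center — the crystal center in pocket mode, the
current-frame center in ligand-tracking mode. Each heavy atom maps to
the voxel `floor((coord − origin)/resolution)`; cells are half-open
`[k, k+1)`, so an atom exactly on the maximum face is dropped. Atoms
sharing a voxel have their 19-channel feature vectors summed. These two
conventions are what make the core invariants *exact* rather than
approximate: channel sums over the grid equal feature sums over in-box
atoms, grids of the two ablation masks add up to the full-complex grid,
and voxelizing a rotated frame equals permuting/flipping the axes of
the original grid for any of the 24 right-angle rotations.

The 19 channels are: one-hot atom type over (B, C, N, O, P, S, Se,
halogen, metal), hybridization (1–3), heavy-atom valence, heteroatom
valence, five pharmacophore flags (hydrophobic, aromatic, acceptor,
donor, ring), partial charge, and a molecule-type channel (−1 ligand,
+1 protein). The channel order is frozen and written into every grid
dataset's metadata. Annotations normally come from a sidecar table;
without one, a deterministic geometric fallback perceives bonds from
covalent radii and sets conservative flags (no ring/aromatic
perception), with charges at 0 — sufficient for self-contained
fixtures, not for production use.

Rotation augmentation draws one rotation per sample per epoch,
uniformly from the 24 right-angle rotations of the cube by default
(continuous SO(3) draws are available). Right-angle draws keep the grid
transformation lossless, and systematic-vs-random parity makes the
cheaper option the default. No rotation is applied at evaluation.

## Model families

All four families are implemented directly in R on top of BLAS GEMM
(im2col convolutions with an exact, hand-derived backward pass; the
whole stack is verified against numerical gradients). Regression is
linear on the pK scale — no output squashing.

* **cnn** — conv/ReLU/maxpool blocks, then a fully connected head.
* **densenucy** — dense blocks instead of plain conv blocks: layer *j*
  convolves the concatenation of the block input and all previous layer
  outputs into `growth` new channels, so a block maps `c` channels to
  `c + layers × growth`; transitions compress with a 1×1×1 convolution
  to `floor(c × θ)` and halve each spatial dimension. Preserving the
  block input alongside the learned features is what mitigates
  information loss through the stack.
* **lrcn** — a shared CNN encoder embeds each frame; an LSTM consumes
  the embeddings step by step; the head reads the final hidden state.
  (The alternative reading — concatenating all frame embeddings into
  one LSTM input — was considered and not implemented; step-by-step is
  the standard LRCN construction.)
* **convlstm** — stacked convolutional LSTM layers unrolled over the
  frames: gates are same-padded 3D convolutions of the input and the
  previous hidden state (`i, f, o` logistic, `g` tanh,
  `c_t = f⊙c_{t−1} + i⊙g`, `h_t = o⊙tanh(c_t)`), with no peephole
  terms, matching the convolutional-LSTM lineage this family adapts.
  The last hidden state is spatially averaged and fed to the head.

The readout for both sequence families is the last-time-step hidden
state, matching the "final prediction after analyzing all frames"
semantics; a mean-over-time readout would be a one-line change but is
not the default. With kernel edge 1 the ConvLSTM cell reduces exactly
to an independent scalar LSTM at every voxel, which the tests exploit
as an oracle.

Exact widths and depths are configuration, not code
(`model_config()`): defaults follow the lineage these architectures
descend from (dense spec 3 blocks × 4 layers, growth 16, compression
0.5; ConvLSTM hidden 32, kernel 3, 2 layers; head 1000–500–200–1).
Desk-scale experiments shrink the same knobs.

## Training

Loss is mean squared error on pK; the optimizer is Adam (the
architecture sources leave both unspecified in the main text, so they
are configuration with logged defaults: lr 1e−3, batch 16). Splits are
assigned at the complex level with a seeded 80/20 shuffle (plus an
optional test reservation); a hard integrity check — every complex in
exactly one split — runs before any optimization, making frame-level
leakage impossible by construction. Validation after each epoch uses
per-complex RMSE (frames averaged per complex first); the retained
checkpoint is the one with the lowest validation RMSE, with optional
early-stopping patience. Per-complex validation was chosen over
per-frame because model selection should reflect the quantity reported
at test time. Ensembles train `n_model_replicates` models (default 10)
that differ only in derived seeds; consensus averages their per-complex
predictions.

## Evaluation protocols

Pearson R and RMSE on pK, Spearman ρ overall and per cluster (clusters
come from the manifest's `cluster_id`; the unweighted mean is taken
over clusters with ≥ 2 members, singletons flagged and excluded).
Undefined correlations (zero variance) are reported as missing, never
coerced to 0.

The **bias gap** retrains the same configuration on partner-ablated
inputs and reports ΔR = mean R(complex) − mean R(ablated) across model
replicates. Ablation removes atoms only; it deliberately does not touch
box centering, so "ligand only" keeps pocket-centered boxes unless
ligand tracking is requested explicitly — the contrast between those
two is itself informative, because a pocket-centered ligand-only model
can still read the ligand's drift through the box while a tracking box
removes that cue.

The **stability statistic** superposes every frame on the pocket heavy
atoms of the first frame (rigid least-squares), measures ligand RMSD
against the first frame, and takes the per-replicate maximum. The
alignment protocol is not externally fixed; pocket-superposition was
chosen because it isolates ligand motion *relative to the binding
site*, which is the quantity of interest. A replicate is stable when
its max RMSD stays below 2 Å; fractions are aggregated per complex and
then averaged within low/high-affinity classes split at the median
label by default (the boundary is configurable).

## The synthetic generator

The generator emulates the *shape* and the *planted relationships* of a
trajectory corpus, not its physics. A complex is a spherical shell of
pocket atoms (radius drawn from 5.5–8.5 Å, 60 atoms in 3-atom
pseudo-residues) plus 8–16 ligand atoms in a 3 Å ball. The label is
`pK = 2 + 0.025 × n_contacts + N(0, 0.3)`, clipped to [0, 14], where
`n_contacts` counts ligand–pocket pairs within 6 Å. A contact-based
signal was chosen over a surface- or energy-based one because a
brute-force oracle is exact and cheap; the chosen coefficients spread
labels over roughly pK 2–12 without saturating the clip. Trajectories
move the ligand as a rigid body on a Gaussian random walk with
per-frame step `0.15 + 0.01 × max(0, 7 − pK)` Å, so low-affinity
ligands wander further — at 50 frames and a 2 Å threshold this yields
stability fractions near 40% (low) vs 55% (high affinity), the
qualitative instability-at-low-affinity relationship the evaluation
protocol is designed to detect. Pocket atoms get 0.05 Å iid jitter so
superposition is exercised. Rigid-body drift means the expected max
RMSD has a closed-form scale, which the Monte-Carlo tests check.

What the generator does *not* emulate: real conformational change
(internal ligand and side-chain degrees of freedom), force-field
physics, solvent, binding kinetics, and the label noise structure of
experimental affinities. Passing tests therefore demonstrate that the
pipeline recovers a planted geometric signal through the full
featurize-train-evaluate chain — not that any architecture ranks real
congeneric series correctly.

## Numerical choices and problem sizes

* Voxel cells are half-open; max-face atoms drop. Colliding atoms sum.
* Rotation matrices are validated to 1e−10 orthonormality; rotations
  preserve pairwise distances to 1e−9 Å.
* Max-pool ties split the subgradient evenly among tied cells (ties are
  measure-zero for real data but common in zero regions of sparse
  grids).
* The ConvLSTM kernel-1 equivalence is asserted to 1e−6; superposition
  agrees with an independent reference implementation to 1e−6.
* Training experiments in the test suite and the acceptance script run
  at desk scale by choice: 60 complexes × 2 replicates × 3 frames, a
  24 Å box at 3 Å resolution (8³ grid), a compact CNN
  (1×1×1 mixing layer, then 3×3×3 convs), 15 epochs. These sizes
  recover the planted signal with held-out per-complex R well above
  0.9 in a few minutes on one CPU; the full-size defaults (120
  complexes × 10 × 50 at 25 Å/1 Å) remain the generator's defaults and
  run unchanged where more compute is available.
* An im2col buffer cap (1.5e8 doubles) switches very large convolutions
  to a slower loop path instead of allocating multi-GB intermediates.

## Storage formats

Grid datasets, trajectories, and model checkpoints use a single-file
binary container (8-byte magic, JSON header, IEEE little-endian double
payload) with splits as groups, datasets `grids`/`labels`/`complex_ids`
and attributes `edge_A`, `resolution_A`, `channels`, `centering`; round
trips are bit-exact and channel-name mismatches are hard errors.
Structures are standard PDB (multi-model PDB for trajectories, read via
bio3d), manifests and predictions are plain CSV with fixed headers.

## Known limitations

* The from-scratch network stack is single-threaded R on BLAS: roughly
  two orders of magnitude slower than a GPU tensor library, so
  full-corpus training (thousands of complexes × 500 frames at 25³) is
  out of reach here; the architecture code paths are identical at every
  scale.
* The fallback annotator does not perceive rings, aromaticity or
  hybridization; real use should supply annotations computed with a
  cheminformatics toolkit.
* Dropout is available but defaults to 0; no batch normalization is
  implemented.
* Clusters and protein families are taken from the manifest, never
  computed.
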