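Package: mdaffinity
Title: Protein-Ligand Binding Affinity from Molecular-Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-grid featurization of protein-ligand binding pockets and
    deep-learning regression of binding affinity (pK) from molecular-dynamics
    trajectories. Implements pocket extraction, a 19-channel atomic encoding,
    cubic-box voxelization with right-angle rotation augmentation, three
    network families (a 3D convolutional network with dense blocks, a
    long-term recurrent convolutional network, and a convolutional LSTM),
    three training regimes (crystal-only, MD data augmentation, and
    whole-simulation spatio-temporal learning), bias-gap and ligand-stability
    evaluation protocols, and a synthetic trajectory generator with a planted,
    recoverable affinity signal for desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    generics,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
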