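Package: nkwell3d
Title: 3D NK-Cell Migration and Cytotoxicity Analysis in Collagen Microwells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for two-channel 3D time-lapse imaging of natural
    killer (NK) cells and tumour target cells embedded in collagen microwells.
    Provides difference-of-Gaussians segmentation with h-minima watershed
    splitting of cell clusters, frame-to-frame probabilistic track linking with
    an anisotropic Brownian motion model, rolling-window mean-squared-displacement
    (MSD) profiling of motility coefficient and anomalous exponent, classification
    of migration modes (transient migration arrest, random, directed), NK-target
    contact detection with cytolytic outcome assignment, and a stochastic
    simulator that generates mode-switching trajectories and renders them into
    noisy anisotropic voxel stacks with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
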