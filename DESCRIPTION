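Package: dynenv
Title: Dynamical Environments from Noisy Particle Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects metastable dynamical environments in noisy,
    high-dimensional particle trajectory data. Computes rotation-invariant
    SOAP power-spectrum descriptors and active-matter order parameters
    (minimum neighbor distance, local velocity alignment), spatially
    denoises per-particle signals, ranks descriptor components by variance
    (with PCA projections), and clusters single-particle time series with
    an iterative Gaussian-peeling ("onion") algorithm across time
    resolutions. Includes diagnostics for information frustration (the
    loss of resolvable states when dimensions are combined), detection
    windows, and sampling-frequency scans, plus synthetic-data generators
    with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
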