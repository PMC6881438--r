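Package: matriex
Title: Multi-Area Two-Photon Imaging with Compound GRIN-Lens Objectives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulation and analysis tools for multi-area two-photon
    calcium imaging through a compound objective made of one low-magnification
    dry objective coupled to several gradient-index (GRIN) miniaturized
    objectives. Provides the paraxial design engine (lens length and back
    working distance, numerical-aperture magnification and capping, a pitch
    solver that conjugates object planes at different tissue depths onto one
    image plane, and scan/zone geometry), a synthetic multi-field-of-view
    movie generator with full ground truth (Poisson events with log-normal
    amplitudes, latent-driver correlation structure, neuropil, rigid motion,
    inter-FOV crosstalk and shot noise), and a calcium-signal analysis
    pipeline (SSD rigid motion correction, ROI trace extraction,
    percentile-baseline delta-f/f, event detection, log-normal amplitude
    fitting, neuropil comparison and intra-/inter-regional Pearson
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
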