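Package: nanomapr
Title: High-Speed AFM DNA Nanomapping with CRISPR-Cas9 Nanoparticle Labels
Version: 0.1.0
Authors@R:
    person("Nanomap", "Developers", email = "nanomapr@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-speed atomic force microscopy (HS-AFM)
    height images of surface-deposited DNA molecules carrying sequence-specific
    CRISPR-Cas9 nanoparticle labels.  Provides image flattening and adaptive
    segmentation, backbone skeletonization and spline contour tracing, label
    detection along the backbone, bp/nm calibration, population statistics on
    the logit scale, reference-map construction from guide sequences, molecule
    orientation and site assignment, and translocation breakpoint calling.
    Includes a physics-based synthetic frame generator (2D worm-like-chain
    conformations, tip dilation, scan-line noise) so every stage is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    rlang,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
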