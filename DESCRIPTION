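Package: coce
Title: Compression Optical Coherence Elastography of Colorectal Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantitative analysis pipeline for compression
    optical coherence elastography (C-OCE) of colorectal tissue. Generates
    mechanically labelled silicone-tissue phantoms and complex-valued OCT
    frame series acquired under compression; estimates interframe strain by
    the phase-gradient "vector method" without phase unwrapping; calibrates
    applied stress through a pre-calibrated reference silicone layer and
    reconstructs maps of the tangent Young's modulus at a standardized
    4 kPa stress; segments the maps into morphological stiffness classes
    (mucosa/stroma, glandular cancer 520-950 kPa, non-glandular cancer
    >950 kPa, non-signal mucin) and calls colorectal tumour subtypes from a
    stiffness-feature decision table; and quantifies morphometric agreement
    between segmentations with Pearson correlation and Bland-Altman limits
    of agreement.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml,
    tiff,
    png,
    igraph,
    arrow
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
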