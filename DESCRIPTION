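Package: astrodomain
Title: Synaptic Puncta and Astrocytic-Domain Density Analysis for Fluorescence Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies bipartite synapse densities and astrocytic-domain
    synapse-density distributions from multi-channel fluorescence micrographs.
    Provides a synthetic-scene generator with known ground truth (Poisson
    puncta, controllable pre/post colocalization, radial density profiles
    around an astrocyte core), an ImageJ-convention pre-processing chain
    (rolling-ball background subtraction, difference-of-Gaussians bandpass,
    despeckling, sharpening, Yen thresholding), size-filtered puncta detection
    with overlap-fraction colocalization calling, a 17-bin Sholl-like layout
    around astrocyte cores with soma exclusion, and the accompanying
    statistical workflow (Shapiro-Wilk gated two-group tests, Holm-Sidak
    correction, one- and two-way ANOVA with Levene check, Games-Howell post
    hoc, repeated-measures ANOVA with omega-squared, trait correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
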