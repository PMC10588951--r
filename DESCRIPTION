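Package: scassembly
Title: Simulation and Quantification of Synaptonemal Complex Head-to-Head Assembly
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the head-to-head self-assembly of the
    transverse filament protein SYCP1 at the synaptonemal complex midline.
    Provides a coarse-grained Brownian-dynamics simulator of two SYCP1
    dimers joined through their N-terminal tips under opposing axial
    steering forces, trajectory metrics (Kabsch superposition RMSD,
    per-residue RMSF, interdimer marker distance, dissociation
    classification), a synthetic generator for SIM-like two-axis image
    stacks and overdispersed tubule apoptosis counts, the matching image
    quantification pipeline (trace straightening, perpendicular line
    profiles, double-Gaussian peak fitting, projection and
    background-subtracted ROI intensity), and the statistical comparisons
    used for such data (Mann-Whitney U, Fisher's exact test on dichotomized
    counts, unpaired t test) together with exact enumeration oracles for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
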