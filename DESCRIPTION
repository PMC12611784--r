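Package: fibromap
Title: Structure-Function Mapping of Fibrotic Hearts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolbox for correlating 3D fibrosis morphology with
    cardiac electrophysiology. Provides optical-mapping signal analysis
    (dF/F0 preprocessing, action-potential kinetics, activation and
    conduction-velocity maps, wavefront dispersion, differential maps),
    three-class tissue segmentation (myocardium, compact and non-compact
    fibrosis) from dual-channel light-sheet volumes, structure-tensor
    estimation of 3D cardiomyocyte orientation with fractional-anisotropy
    gating and helix angles, circular-aware cellular-disarray quantification,
    silhouette-based morpho-functional co-registration, a 1D electrotonically
    coupled myocyte-fibroblast chain simulator, and a reduced-scale monodomain
    tissue simulator with percolation fibrosis. Seeded phantom generators
    supply ground truth for every component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
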