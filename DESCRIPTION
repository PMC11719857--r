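Package: mitoifc
Title: Imaging Flow Cytometry Phenotyping of Mitochondrial Disease Fibroblasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify mitochondrial phenotypes of cultured fibroblasts
    from multi-channel imaging flow cytometry (IFC): event gating (nucleated,
    in-focus, singlet), extraction of five mitochondrial features per cell
    (membrane potential via TMRM with FCCP background subtraction,
    mitochondrial mass via NAO, swelling as total TMRM area, fission/fusion
    state as spot-mask form factor, and nucleus-excluded MitoSox ROS signal),
    normalization to the in-run healthy control with healthy-donor reference
    ranges and abnormality flagging, feature-combination detection rates, and
    cohort-level analysis (UMAP embedding, Ward hierarchical clustering,
    Welch/Mann-Whitney/Spearman/Fisher association tests). A synthetic-data
    module renders single-cell images and cohort feature tables with known
    ground truth so the full pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    cluster,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
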