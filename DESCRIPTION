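Package: osteoflow
Title: Image-Based Finite-Element Analysis of Load-Driven Bone Modeling in Fish Vertebrae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying load-driven bone modeling in anosteocytic fish
    vertebrae: parametric phantom micro-CT volumes of an hourglass-shaped
    vertebral centrum with neural and hemal spines, threshold segmentation,
    voxel-to-tetrahedron meshing (linear and 10-node quadratic elements),
    an attenuation-binned isotropic linear-elastic material model calibrated
    to a nanoindentation modulus range, articular bending and muscle-traction
    load cases, a sparse finite-element solver with von Mises equivalent
    strain output, surface-localization analysis of peak strains,
    Oliver-Pharr analysis of Berkovich indentation curves with Mann-Whitney
    group comparison, and delta-delta-Ct quantification of qPCR expression
    tables with pooled two-sided t tests. Synthetic-data generators with
    known ground truth make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
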