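Package: vertfe
Title: Validation of Voxel Micro Finite Element Models of Vertebral Bodies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for validating voxel-based micro finite
    element (microFE) models of vertebral bodies against digital volume
    correlation (DVC) measurements. Provides readers and writers for 3D
    micro-CT style volumes (TIFF stacks, MetaImage, NRRD), specimen masking
    and segmentation with bone volume fraction and cortical/trabecular
    labelling, a synthetic vertebra phantom generator with known ground-truth
    displacement fields, a grid-based global DVC solver (masked sum of squared
    differences with Laplacian regularisation, Gauss-Newton iterations and a
    coarse-to-fine pyramid), a hexahedral linear-elastic microFE solver with
    DVC-derived boundary conditions and reaction-force extraction, and the
    agreement statistics used to compare predicted and measured local
    displacements: Cook's-distance outlier screening, linear regression,
    RMSE against the identity line, Lin's concordance correlation
    coefficient, axial-force percentage differences and least-squares
    back-calculation of the tissue elastic modulus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    EBImage,
    tiff,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
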