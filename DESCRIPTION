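Package: hybridplan
Title: Dosimetry and Plan-Parameter Regression for Hybrid CFRT + SBRT/SIB
    Lung Radiotherapy Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyses hybrid radiotherapy plans for locally advanced lung
    cancer that combine conventionally fractionated radiotherapy (CFRT) of
    nodal disease with a stereotactic (SBRT) or simultaneous-integrated
    (SIB) boost of the primary tumour.  Provides a shared volumetric data
    model for dose grids and structure masks, anatomical geometry features
    (volumes, volume ratios, minimum 3D surface distances, signed
    cranio-caudal overlap), voxel-wise EQD2 conversion under the
    linear-quadratic model with per-structure alpha/beta resolution,
    hybrid-plan dose summation, DVH plan parameters (conformity and
    homogeneity indices, Vx, Dx, mean and maximum doses), and the
    regression families (multi-linear, S-type, inverse, cubic) that link
    plan parameters to anatomy.  A synthetic thoracic-phantom generator
    and a feature-cohort sampler make the whole analysis testable without
    clinical data.
License: GPL-3
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
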