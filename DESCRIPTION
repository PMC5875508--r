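Package: atlasseg
Title: Hierarchical Multi-Atlas Segmentation of Thoracic and Abdominal CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated segmentation of organs at risk on thoracic and
    abdominal CT volumes by hierarchical multi-atlas label transfer.
    Presegmented atlas scans are aligned to the patient with a two-phase
    affine initialisation followed by masked multi-resolution cubic
    B-spline deformable registration driven by Mattes mutual information;
    the warped per-atlas organ masks are fused voxelwise with the STAPLE
    expectation-maximisation algorithm into an organ probability map; and
    each thresholded organ estimate is refined locally by an automatically
    extracted Hounsfield-unit interval (multi-level Otsu), a threshold
    level-set evolution and a geodesic level-set smoothing step. Includes
    segmentation overlap metrics (Dice, mean surface distance, Hausdorff),
    NIfTI input/output, a synthetic CT phantom generator with known ground
    truth for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'grid.R'
    'volume.R'
    'transforms.R'
    'resample.R'
    'filters.R'
    'morphology.R'
    'nifti.R'
    'mattes.R'
    'registerAffine.R'
    'registerBspline.R'
    'staple.R'
    'otsu.R'
    'levelset.R'
    'refine.R'
    'metrics.R'
    'phantom.R'
    'pipeline.R'
    'watch.R'
    'cli.R'
    'atlasseg-package.R'
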