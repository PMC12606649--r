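Package: fesred
Title: Structure-Based Prediction of Iron-Sulfur Protein Reduction Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multiscale structure-derived descriptors for rubredoxin-type Fe and
    [2Fe-2S] metal sites, and a gradient-boosted regression protocol for
    predicting reduction potentials (mV) from PDB structures. Locates Fe-S
    cofactor sites, computes physicochemical descriptors of the whole protein,
    of the sphere around the cluster barycenter, and of the local environment of
    each cofactor atom, and assembles fixed-length feature vectors. Provides
    nested cross-validated training with a fixed hyperparameter grid, radii
    scanning, spatial-scale ablations, leave-protein-out and leave-mutant-set-out
    tests, SHAP feature attribution, and a synthetic toy-structure generator for
    fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    xgboost,
    glmnet,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Collate:
    'properties.R'
    'structio.R'
    'descriptors.R'
    'datasetio.R'
    'synthetic.R'
    'mlcore.R'
    'interpret.R'
    'fesred.R'
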