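Package: sidefall
Title: Patient-Specific Sideways-Fall Simulation and Hip-Fracture Risk
    Classification from DXA-Like Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for hip-fracture risk analysis from
    2D areal bone mineral density (DXA-like) scans of the proximal femur.
    Generates synthetic two-group cohorts (fractured / control) with
    realistic clinical, geometric and densitometric structure; measures
    femoral morphometry (neck width, hip axis length, neck-shaft angle and
    related quantities) from segmentation masks; computes the fall-impact
    load chain (peak impact force, soft-tissue attenuation, hip pressure);
    solves a patient-specific 2D plane-strain linear-elastic finite element
    model of the sideways fall with BMD-derived heterogeneous materials and
    PMMA pads; reduces the solution to a canonical 39-attribute vector
    including load-to-strength ratio, femoral strength and fracture risk
    indices; selects predictive attributes by principal component
    contribution analysis combined with Pearson/Spearman correlation
    thresholding; and benchmarks logistic regression, support vector
    machine, decision tree and random forest classifiers on SMOTE-balanced
    training sets with sensitivity, specificity and accuracy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    e1071,
    kernlab,
    rpart,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
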