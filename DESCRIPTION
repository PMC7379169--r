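Package: peckmech
Title: Comparative Woodpecker and Human Head-Impact Biomechanics in 2D
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A self-contained two-dimensional plane-strain explicit-dynamics
    finite-element pipeline for comparing brain biomechanics of a pecking
    woodpecker and a human under identical rotational head kinematics.
    Provides parametric simplified head geometries (beak, hyoid, skull,
    flesh, brain for the woodpecker; skull, face, neck, subarachnoid space,
    brain for the human), an Ogden hyperelastic brain with quasilinear
    viscoelastic (Prony-series) relaxation, reconstruction of the pecking
    cycle drive from tabulated phase anchors, an explicit central-difference
    solver with reduced-integration quadrilaterals and hourglass control,
    strain and stress injury metrics (maximum shear strain, maximum
    principal strain, von Mises stress), field-comparison statistics
    (Pearson r, regression slope, correlation score), axonal-strain and
    shear-stress injury-threshold assessment, and a head-size
    acceleration-scaling study.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
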