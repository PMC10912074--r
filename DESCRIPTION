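Package: dwbpet
Title: Dynamic Whole-Body PET Kinetic Modeling, Patlak Parametric Imaging
    and Lesion Visibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of dynamic whole-body PET studies with
    metabolized radiotracers such as 16alpha-[18F]fluoroestradiol. Provides a
    synthetic-data generator (multi-pass frame schedules, metabolite-corrected
    blood input functions, two-tissue compartment tissue kinetics, 4D digital
    phantoms with spherical lesions), image-derived input function extraction
    with parent-fraction and plasma-to-whole-blood correction, closed-form
    forward modeling and bounded multi-start fitting of reversible and
    irreversible two-tissue compartment models with AIC model comparison,
    Patlak graphical analysis including voxelwise Ki/V parametric images, SUV
    image synthesis, and lesion detectability statistics (target-to-background
    and contrast-to-noise ratios with paired log-ratio comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
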