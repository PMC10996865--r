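Package: phoskin
Title: Intradialytic Phosphate Kinetics with a Linear Clearance-Reduction Component
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-compartment model of intradialytic phosphate kinetics in
    haemodialysis with an individual linear clearance-reduction (coagulation)
    component. Provides anthropometric volume determination (Watson total body
    water partitioned into plasma water, remaining extracellular and
    intracellular fluid), dialyser phosphate clearance estimation from paired
    dialysate and plasma samples, fixed-step forward simulation of the
    compartment system, RMSE-based fitting of the mass-transfer coefficients
    and the clearance-reduction slope, model comparison via squared Pearson
    correlation and Fisher r-to-z tests, phosphate-removal summaries, and a
    synthetic patient-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
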