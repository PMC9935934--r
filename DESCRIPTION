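Package: trochfem
Title: Finite-Element Instability Analysis of Trochanteric Hip Fracture
    Wall Defects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds parametric finite-element models of a cephalomedullary
    nail (PFNA-type) fixation of trochanteric hip fractures with configurable
    cortical wall defects (medial, lateral, their anterior/posterior halves,
    and the posterior coronal defect), assigns bone material properties from
    a synthetic Hounsfield-unit field through density and elastic-modulus
    calibration, solves small-strain linear-elastic tetrahedral models under
    static and quasi-static gait hip-contact loads with penalty contact
    across the fracture surface, extracts biomechanical outcome indicators
    (implant von Mises stress peaks, bone principal-strain peaks, risky
    tensile and compressive bone volumes, head-vertex displacement, fracture
    surface gap), and scores the models with per-indicator min-max relative
    instability ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
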