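Package: infantfem
Title: Finite-Element Analysis of the Developing Infant Femur
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for subject-specific finite-element analysis of immature long
    bones whose epiphyses are still largely cartilaginous. Generates parametric
    voxel phantoms of the infant femur (mineralised diaphysis plus non-ossified
    proximal epiphysis), builds 10-node tetrahedral meshes, maps CT-style
    intensities to element-wise Young's moduli by volume-integrated averaging,
    derives Neo-Hookean and poroelastic parameters for the ossifying region,
    solves static torsion and uniaxial load cases (linearised, hyperelastic and
    transient poroelastic modes), and post-processes principal-strain fields
    into a strain-limit moment-to-fail of the diaphysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
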