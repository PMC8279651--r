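Package: crystalhop
Title: Basin-Hopping Crystal Structure Prediction for Rigid Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Global optimization of molecular crystal structures by
    basin-hopping with a dynamically optimized triclinic unit cell. Rigid
    molecules are described by fractional center-of-mass coordinates and
    absolute angle-axis orientations; the lattice energy combines an
    anisotropic site-site repulsion-dispersion model, Ewald electrostatics
    and a Weeks-Chandler-Andersen penalty on near-degenerate cell angles,
    with analytic gradients in all 6N+6 degrees of freedom. Includes LBFGS
    local minimization, Metropolis acceptance with adaptive temperature,
    deduplicated minima archives, Niggli cell reduction, polymorph matching,
    mean first-encounter-time statistics, and CIF import/export. Ships a
    synthetic benzene parameter set for demonstration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
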