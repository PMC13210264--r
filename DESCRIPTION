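Package: gofold
Title: Structure-Based (Go-Model) Simulation and Analysis of RNA Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds all-atom structure-based (Go-type) models from a folded
    RNA structure, including the native contact map and a 12-10 contact
    potential with native-geometry bonded terms, and samples folding
    trajectories with a BAOAB Langevin integrator. Provides order-parameter
    analyses over the resulting ensembles: the fraction of native contacts Q
    (global and per structural domain), free-energy profiles F(Q),
    domain-folding pathway classification, residue-residue contact frequency
    maps, base center-of-mass distance shifts, and heavy-atom hydrogen-bond
    counts, together with synthetic stem-loop fixtures (hairpin and a toy
    tRNA with aas/asl/dsl/tsl/vl domains) and support for the
    N2,N2-dimethylguanosine (m2,2G) base modification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
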