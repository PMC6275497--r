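Package: nascentfold
Title: Coarse-Grained Simulation and Kinetic Modelling of Cotranslational
    Protein Folding on the Ribosome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how a protein domain folds while tethered to the
    ribosome by a nascent-chain linker. Builds structure-based (Go-type)
    coarse-grained models of a protein domain attached through an unstructured
    linker to a fixed ribosome scaffold, propagates them with constrained
    Langevin dynamics, and performs umbrella sampling along the fraction of
    native contacts Q. Weighted-histogram (WHAM) reweighting yields free-energy
    profiles, folded populations, and mean tether forces per linker length;
    a Bell-model arrest-escape kinetic scheme (solved both by kinetic Monte
    Carlo and by a preequilibrium closed form) converts these into predicted
    arrest-peptide force profiles, the fraction full-length protein f_FL(L).
    Transition-path statistics (phi-values, conditional contact importance)
    quantify the folding mechanism on and off the ribosome. Synthetic fixtures
    (toy foldable chains, a toy exit tunnel, labelled trajectory ensembles)
    make the whole pipeline testable without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    generics,
    stats,
    utils,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
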