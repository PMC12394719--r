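Package: condage
Title: Coarse-Grained Simulation and Analysis of Protein Condensate Ageing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-resolution coarse-grained simulation of protein and peptide
    condensates, together with a non-equilibrium engine for the disorder-to-order
    ("ageing") transition of low-complexity aromatic-rich kinked segments (LARKS)
    into cross-beta-sheet assemblies, and the downstream analyses used to screen
    peptides that decelerate condensate ageing: phase boundaries and critical-point
    fits, secondary-nucleation kinetic fitting of ageing curves, Green-Kubo
    viscoelasticity, intermolecular contact maps, chain conformational and
    diffusion observables, and a peptide-screening campaign driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    igraph,
    seqinr,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
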