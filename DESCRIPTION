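Package: ribotunnel
Title: Nascent-Chain Folding Simulations in Rigid Ribosomal Exit Tunnels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained structure-based (Go-model) Langevin dynamics of
    nascent proteins grown residue-by-residue at the peptidyl-transferase
    center inside rigid all-atom ribosomal exit tunnels, together with
    grid-probe tunnel volumetrics (cavity volume, surface-to-volume ratio,
    axial radius profile, constriction sites), trajectory analytics
    (trapping and escape classification, folding detection) and open-chain
    knot detection by KMT reduction and the Alexander determinant. Includes
    seeded generators of synthetic tunnels, toy native models and
    parametric knotted curves so every stage is testable without
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
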