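Package: hypoxsig
Title: Hypoxia-Tumor Signaling Network Simulation and Virtual-Cell Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles an integrated ordinary-differential-equation model of
    HIF-1alpha hypoxia signaling coupled to a VEGF/EGF tumor signaling network
    through VEGF mRNA and ATP-dependent phosphorylation, simulates
    Latin-hypercube ensembles of virtual tumor cells under oxygen step changes
    and ATP-competitive kinase or VEGF-binding inhibition, categorizes pERK,
    pAkt and VEGF responses relative to normoxic baselines, and explains the
    response categories with decision trees. Ships a reconstructed
    189-species/86-reaction model in a tabular schema, closed-form toy
    fixtures, steady-state detection on top of stiff integration, and
    dose-response utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    lhs,
    rpart,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
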