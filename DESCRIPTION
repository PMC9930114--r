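Package: rhpseq
Title: Monte Carlo Simulation and Sequence Analysis of Random Heteropolymers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates batches of explicit random-heteropolymer (RHP) sequences
    under the multicomponent Mayo-Lewis terminal model of reversible-deactivation
    radical polymerization, with tunable number of chains, degree of
    polymerization, conversion and polydispersity. Provides a
    bioinformatics-style analysis stack applied identically to simulated
    polymers and to protein sequences translated into monomer space: per-chain
    composition distributions with feed-normalized FWHM (chemical
    heterogeneity), HLB-based hydrophobic/hydrophilic run-length segment
    statistics, sliding-window hydropathy profiles, and a specific-segment
    motif search for hydrophobic runs with one embedded hydrophilic marker.
    Includes a reverse recipe solver that converts batch targets into bench
    reagent masses and volumes, plain-text batch file IO, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
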