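Package: notchemt
Title: Coupled Notch-Delta-Jagged and EMT Circuit Simulation on Hexagonal Cell Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of juxtacrine Notch-Delta-Jagged signalling
    coupled to the core epithelial-mesenchymal transition (EMT) regulatory
    circuit (miR-34/SNAIL and miR-200/ZEB). Provides the single-cell ordinary
    differential equation model built from shifted-Hill regulation and
    combinatorial microRNA-mRNA binding, brute-force multistability analysis
    (bifurcation sweeps, Notch/Delta nullclines, two-parameter phase diagrams),
    a synchronous hexagonal-lattice tissue simulator in which every cell senses
    the ligands and receptors presented by its six neighbours, and quantitative
    pattern metrics (phenotype fractions, connected-component cluster sizes,
    unlike-neighbour fraction, mean NICD). Reproduces lateral inhibition
    (Delta-dominated 'salt-and-pepper' dispersion) versus lateral induction
    (Jagged-dominated clustering of hybrid epithelial/mesenchymal cells).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
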