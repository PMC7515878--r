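Package: fibrilnet
Title: Network Hamiltonian Models of Amyloid Fibril Self-Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained modelling of amyloid fibril formation on
    aggregation graphs, in which vertices are protein monomers and edges are
    non-covalent inter-monomer contacts. Implements a nine-term network
    Hamiltonian over topological bonding motifs (edges, two-stars, null and
    edgewise shared partners, and five- to seven-cycles), the corresponding
    exponential-family random graph (Boltzmann) equilibrium distribution with
    exact enumeration on small systems and Metropolis-Hastings sampling, and a
    continuous-time kinetic extension that simulates fibrillization
    trajectories from free monomers via exponentially distributed waiting
    times over single-bond (Hamming) transitions. Includes generators and
    classifiers for the five fibril topology classes observed in the Protein
    Data Bank (1-ribbon, 2-ribbon, 1,2 2-ribbon, double 1,2 2-ribbon,
    3-prism), induced fibrillar component extraction, per-frame aggregation
    metrics, segmentation of trajectories into mechanistic epochs
    (Condensation, Local Ordering, Nucleation, Fibril Growth, Maturation),
    and a census of defect-related bonding motifs and breakage events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    yaml,
    rlang,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
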