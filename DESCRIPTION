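Package: flexcore
Title: Coarse-Grained Integrative Modelling of Flexible Regions in
    Multi-Domain Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models multi-domain protein complexes whose deposited
    structures leave large flexible regions unresolved.  Builds a
    C-alpha bead model in which resolved residues form a quasi-rigid
    Go-like core and unresolved residues form flexible chains, runs
    Langevin dynamics with stochastically switched sigmoidal
    cross-link distance restraints derived from cross-linking mass
    spectrometry, maps cross-links onto structures and ensembles
    against the ~25 Angstrom lysine cross-linker distance limit, and
    reweights conformational ensembles against small-angle X-ray
    scattering data by sparse non-negative least squares on a
    Debye-formula scattering calculator.  Includes Guinier, Kratky and
    pair-distance-distribution SAXS diagnostics and a synthetic-data
    generator producing structures, cross-link tables and SAXS curves
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    grDevices,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
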