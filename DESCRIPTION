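Package: hodgeflow
Title: Hodge Laplacian Spectra and HodgeRank Folding Analysis for
    Biomolecular Structures and Hi-C Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Represents biomolecular structures and Hi-C contact maps as
    Vietoris-Rips simplicial complexes and analyses them with discrete Hodge
    theory.  Boundary matrices and combinatorial Hodge Laplacians yield Betti
    numbers and homology generators; the HodgeRank orthogonal decomposition of
    sequence-signed edge flows into gradient, curl and harmonic parts yields
    total and average inconsistency (TI/AI) indices that quantify the folding
    and compactness of protein and DNA chains and the likelihood that a Hi-C
    region is a topologically associating domain (TAD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    bio3d,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
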