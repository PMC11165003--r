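Package: syncpath
Title: Predicting the Transition to Synchronization in Networked Dynamical
    Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spectral prediction of the full path to synchronization of a
    network of identical dynamical units.  From the eigenvalues and
    eigenvectors of the graph Laplacian the package derives the ordered
    sequence of cluster-synchronization events (which nodes cluster, and at
    which coupling strength), computes the Master Stability Function of
    built-in chaotic flows (Roessler, Lorenz) by Benettin's method to obtain
    the critical parameter nu*, verifies predictions by direct integration of
    the coupled network, and generates synthetic networks with planted,
    analytically known cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
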