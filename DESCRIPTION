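Package: rnaneighbors
Title: Maximum Expected Accuracy Structural Neighbors of RNA Secondary
    Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for exploring the structural neighborhood of an RNA
    secondary structure at fixed base-pair distance.  Implements a dynamic
    program that computes, simultaneously for every base-pair distance k
    from a reference structure, the maximum expected accuracy (MEA)
    k-neighbor, a pseudo-Boltzmann partition function over MEA scores with
    stochastic sampling from the MEA ensemble, a McCaskill-style partition
    function and base-pair probabilities under a simple additive pair
    energy model, Boltzmann ensemble sampling, and a closed-form minimal
    sample size guaranteeing uniform accuracy of sampled distance-class
    frequencies across all distance bins.  Includes exhaustive enumeration
    oracles for small sequences, dot-bracket and FASTA input, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
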