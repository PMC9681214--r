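Package: connectax
Title: Comparative Connectomics Across a Mammalian-Style Taxonomy
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing whole-brain structural connectomes across
    species in a common frame of reference. Quantifies similarity between
    connectomes via the eigenspectrum of the normalized graph Laplacian and
    via multiscale topological feature vectors (binary and weighted, local
    and global graph measures), compares intra- versus inter-taxon distances
    with Welch and Mann-Whitney tests and their effect sizes, and
    characterizes conserved global organization: small-worldness against
    degree-preserving rewired nulls, consensus Louvain community structure,
    rich-club detection with permutation significance, and four-way edge
    classification. Includes a synthetic taxonomy generator (stochastic
    block model archetypes with bilateral organization, spatial coordinates
    and distance-dependent log-normal weights) so the entire pipeline is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
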