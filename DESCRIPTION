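Package: gule
Title: Credibility-Graph Spectral Clustering with Adaptive Graph Cuts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-layer unsupervised clustering and visualization preparation
    built on class-consistent credibility graphs. Local class consistency is
    extracted into a sparse credibility graph, propagated globally by an
    adaptive spectral graph cut that interpolates between the normalized cut
    and ratio association according to the graph's average connection
    strength, and labels are read off a completely-positive-factorization
    rotation of the dominant eigenbasis. Includes consensus-based distance
    metric selection, internal and external clustering indices, coupled
    distance matrices for topology-preserving embeddings, seeded synthetic
    benchmark generators, and numeric diagnostics for the perturbation
    theory underlying the method.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    cluster,
    graphics,
    grDevices,
    methods,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
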