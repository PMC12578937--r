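Package: solspace
Title: Solution Space Exploration for Community Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to explore and characterise the solution space of
    stochastic community-detection algorithms. Repeated runs under
    information-preserving permutations of the input ordering are coupled
    with a sequential Dirichlet-Multinomial posterior over the unique
    partitions discovered, providing principled stopping rules
    (stabilisation and separation of credible intervals), a five-class
    taxonomy of solution spaces (Single, Dominant, Multiple, Sparse,
    Empty), pairwise agreement matrices with outlier scoring, and
    ring-of-cliques benchmark generators with input-ordering bias
    diagnostics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
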