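Package: phenospread
Title: Unsupervised Graph-Based High-Throughput Phenotyping from Clinical Concept Extractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines patient phenotype status from automated concept
    extraction output (UMLS CUIs with confidence scores) without training
    data. Builds reflective random indexing semantic vectors for concepts
    from a patient note corpus, grows a breadth-first nearest-neighbor
    graph around a seed phenotype concept weighted by vector cosines,
    curates the graph against thesaurus and literature relation databases,
    and classifies each patient by spreading activation from mentioned
    concepts to the seed node. Includes a synthetic corpus generator with
    planted seed-associated concept clusters, evaluation against gold
    labels, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    utils,
    stats,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
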