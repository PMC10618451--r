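Package: godomains
Title: Function-Aware Protein Domain Embeddings for GO Term Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns dense, function-aware embeddings of protein domains from
    domain-Gene Ontology (GO) co-occurrence conditional probabilities with a
    self-supervised dual-embedding network, embeds proteins as the mean of
    their domain embeddings, and transfers GO annotations with a
    distance-weighted k-nearest-neighbour model optionally fused with
    BLAST bit-score and protein-protein-interaction evidence. Includes an
    OBO ontology parser with annotation propagation, semantic-similarity
    scores (simRel, GOscore, funSim), the protein-centric CAFA evaluation
    metrics (Fmax, AUPR, Smin), and a seeded synthetic-data generator with
    planted domain-to-GO association structure for offline testing.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
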