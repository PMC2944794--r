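Package: predictogram
Title: Predicted Protein-Association Networks and Their Experimental Dark Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds integrated protein functional-association networks
    ("Predictograms") from heterogeneous ab-initio prediction datasets by
    weighted Fisher combination of per-method p-values, compares them against
    evidence-count experimental networks ("Knowledgegrams"), and quantifies the
    experimentally uncharacterised ("dark") fraction of the predicted
    interactome. Includes right-tailed Gaussian score normalisation, simulated
    annealing weight optimisation, Resnik information-content semantic
    similarity over ontology DAGs, random-model precision/recall benchmarking,
    scale-free topology diagnostics with weight- and adjacency-randomisation
    nulls, dark-hub ranking by degree enrichment, ranked-list hypergeometric
    functional enrichment, and second-order association prediction from shared
    interaction profiles. A synthetic-world generator provides planted truth
    for end-to-end evaluation.
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
    Matrix,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
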