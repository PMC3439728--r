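Package: setopics
Title: Side-Effect Topic Models for Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies drug-repositioning candidates from the similarity of
    side-effect profiles documented in drug labels. Extracts standardized
    adverse-event terms from the safety sections of labels, fits a latent
    Dirichlet allocation topic model by collapsed Gibbs sampling, selects the
    number of topics with a PCA eigenvalue information-loss criterion,
    computes symmetrized Kullback-Leibler distances between per-drug topic
    distributions, and evaluates nearest-neighbor drug pairs for shared
    indications, Boxed-Warning replacement candidates, and enrichment of
    ATC therapeutic categories. Includes a fully seeded synthetic label-corpus
    generator with ground-truth topic mixtures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    rlang,
    jsonlite,
    readr,
    ggplot2,
    generics,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
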