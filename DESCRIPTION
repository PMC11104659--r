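Package: cravingminer
Title: Mining Craving Mentions and Their Contexts in Recovery-Forum Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for studying alcohol-craving onset in posts from
    online sobriety forums. Detects craving posts with an
    embedding-expanded lexicon compiled into word-form patterns,
    quantifies per-author craving contexts (social company, locations,
    emotions), analyses posting times and sobriety-badge day counts,
    and clusters craving posts into themes with a collapsed-Gibbs
    latent Dirichlet allocation model selected by held-out perplexity
    and NPMI coherence. Ships a synthetic forum-corpus generator with
    full ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
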