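Package: targetrank
Title: Therapeutic Target Ranking from Causal Language Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ranks candidate gene targets for a disease by querying a causal
    language model for next-token probabilities constrained to a token trie
    built over an official gene-symbol lexicon. Gene probabilities are
    accumulated by iterative trie expansion with configurable per-step and
    final (token-length) normalization. Includes top-k enrichment validation
    statistics (enrichment log fold change and hypergeometric p-values),
    cosine-similarity embedding graphs with shortest-path permutation tests,
    a literature co-mention baseline ranking, multi-list intersection
    analysis, and a fully deterministic synthetic language model for offline
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    igraph,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
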