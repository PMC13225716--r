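Package: golgiscreen
Title: In Silico Screening of Candidate Regulators of Golgi Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a comparative in-silico screen for
    candidate regulators of Golgi organization in cancer cell lines. Starting
    from a Golgi-associated gene universe (annotation-derived plus curated),
    the pipeline screens differential expression between Golgi-phenotype
    discordant cell-line pairs with a symmetric fold-change threshold and an
    adaptive top-N cap, scores each shortlisted gene by literature knockdown
    concordance (0/1/2) and by its count of Golgi-associated primary
    interactors in a confidence-filtered protein-interaction network, selects
    candidates on the combined score, and intersects candidate lists across
    cancer types. Seeded synthetic-data generators with planted ground truth
    emulate all five inputs so every stage is testable without downloads.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
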