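Package: sscd
Title: Semi-Supervised Community Detection with Pairwise Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects communities in undirected networks by symmetric
    nonnegative matrix factorization with two graph-regularization
    penalties that encode must-link and cannot-link pairwise
    constraints as positive and negative links. Includes constraint
    budgeting and sampling from ground-truth partitions, NMI and
    Purity scoring, three comparison factorization methods, a
    planted-partition generator for fully reproducible benchmarks,
    and prior-percentage / regularization-weight sweep protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
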