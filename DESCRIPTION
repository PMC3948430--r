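Package: trpmine
Title: Mining Transcriptional Regulatory Pathways from TF-Gene Evidence Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds condition-specific transcriptional regulatory networks from
    literature-curated TF-gene binding (TFB) and TF-gene regulation (TFR)
    evidence tables, enumerates all transcriptional regulatory pathways (TRPs)
    or all shortest TRPs between queried TF-gene pairs, scores each pathway by
    the proportion of along-path pairs carrying TFR evidence, classifies
    pathways as known or putative against an abstract corpus, and assembles
    search, browse and detail reports. Includes deterministic synthetic
    evidence-table generators for testing, Graphviz DOT export, and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
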