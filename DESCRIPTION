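Package: ddimesh
Title: Mining Drug-Drug Interaction Mechanisms from MeSH-Indexed Literature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes drug-drug interaction (DDI) mechanisms from PubMed
    literature indexed with Medical Subject Headings (MeSH). Partitions a
    drug's articles into DDI-related and DDI-unrelated groups by interaction
    descriptors, identifies DDI-enriched drug, protein and phenomena terms
    with a resampling-based null distribution and Z-statistic p-values,
    builds term-article incidence and term-term co-occurrence matrices with
    hierarchical clustering, constructs weighted term networks for drug
    pairs, and validates ranked terms against gold-standard labels with ROC
    curves. Includes a synthetic MEDLINE corpus generator with planted
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
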