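Package: ivtseq
Title: Terminal-Sequence Profiling of In Vitro Transcription Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the 5'- and 3'-end homogeneity of RNA
    synthesized by single-subunit phage RNA polymerases from adaptor-ligated
    deep-sequencing reads. Provides anchored extraction of 5'-terminal windows
    and 3'-terminal segments, frequency tables and size distributions,
    classification of termini into templated, shifted, non-templated-addition
    and self-templated (fold-back) categories, a run-off fidelity statistic,
    a mechanistic fold-back extension model with exact-stem hairpin detection,
    a promoter-candidate genome filter, and a synthetic read generator with
    per-read ground truth that emulates start-site heterogeneity, 5' extra-G
    addition, premature hairpin termination, non-templated 3' additions,
    self-templating extension and degradation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
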