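Package: domfam
Title: Domain-Signature Classification of Plant Transcription Factor,
    Transcriptional Regulator and Chromatin Regulator Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein or nucleotide sequences into plant
    transcription factor (TF), transcriptional regulator (TR) and chromatin
    regulator (CR) families by evaluating curated boolean "must-have" /
    "prohibited" domain-signature rules over per-protein InterPro domain
    annotation sets. Includes a rule-language parser and evaluator, a
    six-frame translation front end for nucleic-acid input, readers for
    InterProScan 5 tab-separated output, a prediction-versus-reference
    benchmark comparator (matches / conflicts / missed / newly predicted),
    a synthetic fixture generator with planted ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
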