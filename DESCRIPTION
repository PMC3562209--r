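Package: rbpscreen
Title: RNA-Protein Interaction Screening on Protein Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for protein microarray screens in which a
    fluorescently labeled RNA is incubated on an array of recombinant
    proteins spotted in duplicate. Parses GenePix Results (GPR/ATF) scans,
    quantifies per-spot signal-over-background ratios, calls significant
    RNA-protein interactions with a dual fold-change and Z-score filter,
    removes strand-nonspecific binders by antisense subtraction, builds and
    clusters binary interaction matrices, computes replicate concordance,
    hit-set overlap significance and annotation-term enrichment with
    Benjamini-Hochberg correction, checks dye-labeling efficiency, and
    simulates whole arrays with planted ground-truth interactions for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
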