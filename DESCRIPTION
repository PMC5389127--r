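Package: hotpepr
Title: Conserved-Peptide Discovery and Annotation of Enzyme Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers groups of related proteins sharing short conserved
    peptides within enzyme families (Peptide Pattern Recognition), annotates
    unknown protein sequences to those families and groups by exact peptide
    matching (Hotpep), and predicts enzymatic function as EC numbers from the
    experimentally characterized members of each group. Includes pairwise
    annotation-comparison statistics (sensitivity, precision, F1) and a
    synthetic enzyme-family generator with planted hexapeptide motifs so the
    whole discovery-annotation-evaluation stack is testable without external
    databases. All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    ggplot2,
    generics,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
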