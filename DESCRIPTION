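Package: dminer
Title: De Novo Inference of Immunoglobulin D Genes from CDR3 Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for de novo reconstruction of immunoglobulin D (diversity)
    germline genes from antibody CDR3 repertoires. Implements a probabilistic
    model of CDR3 generation by V(D)J recombination (exact likelihood for the
    one-sided trimming model and a full simulator with truth labels), seed
    k-mer selection, chi-square-driven bidirectional seed extension with
    branching, filtering of V/J-derived extensions by relative position,
    similarity-graph clique merging of redundant candidates, classification of
    candidates against a germline database, and downstream D-gene usage,
    decoy-allele robustness, over-usage, and V-gene haplotyping analyses.
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
    igraph,
    purrr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
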