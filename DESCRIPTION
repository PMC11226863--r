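Package: codonlm
Title: Codon Optimization with a Dual-Stream Masked Language Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design of synonymous coding sequences with a dual-stream
    attention encoder in which amino-acid tokens provide the queries and
    codon tokens the keys and values of a cross-attention mechanism. The
    model is trained as a masked language model under a stepwise
    sequence-masking curriculum that progressively replaces whole codon
    sequences with zero placeholders, until codons are predicted from the
    protein alone. Includes corpus construction from coding sequences
    (expression filtering, codon-adaptation-index filtering, admixture of
    "one amino acid-one codon" optimized sequences), a synthetic corpus
    generator with planted codon-usage bias, the codon adaptation index,
    and an evaluation battery (codon accuracy, CAI, codon and bicodon
    usage correlation, optional minimum-free-energy adapter).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
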