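Package: mitochar
Title: Mitogenome Characterization, tRNA Cloverleaf Folding and
    Maximum-Likelihood Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes annotated vertebrate mitochondrial genomes the way
    mitogenome announcement papers report them: per-gene lengths,
    intergenic/overlap spacing, ATN start codons and complete or incomplete
    (T--/TA-) stop codons under the vertebrate mitochondrial code, per-region
    base composition with AT and GC skew, and relative synonymous codon usage.
    Predicts tRNA cloverleaf secondary structures by exact constrained stem
    search, including DHU-armless folds. Infers maximum-likelihood phylogenies
    under GTR+F+I+G4 with Felsenstein pruning, NNI search, nonparametric
    bootstrap, and monophyly/paraphyly/polyphyly classification, plus a
    built-in progressive aligner. A seeded synthetic-data module generates
    annotated mitogenomes and sequences evolved along known trees so every
    stage is testable against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
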