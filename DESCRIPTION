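Package: paralogEvol
Title: Molecular Evolution and Expression Divergence of Duplicated Gene
    Subfamilies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of the evolutionary and regulatory divergence of
    small duplicated gene subfamilies, such as the tomato
    phytochrome-interacting factor (PIF) clades. Provides Nei-Gojobori
    dN/dS distances with Jukes-Cantor correction, molecular-clock dating
    of duplication events, the effective number of codons (Nc),
    Goldman-Yang codon site models (M0, M1a, M2a) with likelihood-ratio
    tests and Bayes empirical Bayes identification of positively
    selected sites, neighbor-joining trees with bootstrap support, IUPAC
    consensus scanning of promoter fragments with paralog motif
    comparison, and permutation-tested qPCR expression profiling.
    Includes simulators that generate codon alignments, promoters and
    qPCR experiments with known ground truth so every stage of the
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
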