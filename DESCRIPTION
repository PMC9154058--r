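Package: modfree
Title: Classification and Divergence Analysis of Duplicated Protein Domains
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for distinguishing evolutionary classes of duplicated
    protein domains (modular domains embedded in a larger structural module
    versus free-standing N-terminal repeats) from multiple sequence
    alignments. Provides representative-guided merging of per-orthogroup
    alignments into a master alignment, greedy identity-based dereplication,
    one-hot encoding of alignment columns, elastic-net penalized logistic and
    multinomial regression fitted by proximal gradient descent with
    cross-validated grid search and a confidence-interval sparsest-model
    selection rule, LOGO-style weight and per-column frequency tables,
    Poisson- and gamma-corrected amino-acid distances summarised within and
    between orthogroups, likelihood-ratio tests for site-model comparisons,
    and Benjamini-Hochberg false discovery rate control. A synthetic-data
    module generates alignments with planted class-diagnostic columns,
    orthogroup splits of a known master alignment, and sequence pairs
    diverged by a known expected number of substitutions per site, so every
    stage of the pipeline is testable against ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
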