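Package: endloop
Title: Exterior-Loop Contour Length Analysis of mRNA Secondary Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the contour length of the exterior loop of predicted
    minimum-free-energy RNA secondary structures as an index of the
    end-to-end separation of mRNA molecules, and compares native mRNA
    populations against a uniform-composition random-sequence null model.
    Provides readers for FASTA, GenBank flat files, Vienna dot-bracket and
    mfold CT structure formats; eligibility filtering of full-length mRNAs
    (UTR presence, polyadenylation signal, poly-A start, length window);
    wrappers around the ViennaRNA folding programs; Gaussian histogram
    fits with a 1/e half-width convention, 95% upper bounds, width
    scaling, sigma-confidence, Welch's unequal-variance test and Pearson
    correlation with linear fits and confidence bands; and an end-to-end
    survey pipeline with per-species aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    graphics,
    utils,
    Biostrings,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: ViennaRNA (RNAfold, RNAsubopt on PATH) for structure
    prediction; structure-file parsing and statistics work without it.
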