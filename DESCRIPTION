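Package: pigblup
Title: Genomic Prediction Across Combined Pig Populations with GBLUP, ssGBLUP
    and Genomic-Feature BLUP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for genomic prediction in multi-population
    pig breeding programmes. Simulates diverged populations of one breed with
    multi-generation pedigrees, chip- and sequence-density marker panels and
    shared QTL; derives corrected phenotypes from pedigree BLUP with a
    reliability filter; builds pedigree (A), genomic (VanRaden G), adjusted
    (Ga), blended (Gw) and single-step (H inverse) relationship matrices;
    estimates variance components by AI-REML with EM fallback and solves
    Henderson's mixed model equations for GBLUP, ssGBLUP and genomic-feature
    BLUP; selects feature markers from a mixed-linear-model association scan
    or from QTL windows; applies marker quality control (MAF, call rate, LD
    pruning) and imputation-accuracy metrics; and evaluates prediction
    accuracy over reference-set by method by panel scenario grids with
    forward (birth-date) validation splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
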