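Package: brcaness
Title: BRCAness Detection from Genomic Scar Scores and DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for detecting the BRCAness phenotype (homologous
    recombination deficiency without necessarily a BRCA1/2 mutation) in
    tumor cohorts. Computes genomic-scar scores (HRD-LOH, HRD-TAI, HRD-LST
    and two percent-of-genome-changed variants) from copy-number segment
    tables and labels samples by threshold; ranks DNA-methylation array
    probes by the delta-variance statistic with a label-permutation null
    and sample-exclusion diagnostics; trains a class-balanced random-forest
    classifier evaluated with feature selection nested inside stratified
    cross-validation (pooled confusion matrices and combined ROC/AUC); and
    runs classic preranked gene-set enrichment with permutation-based
    nominal p and family-wise error rates. Seeded synthetic-data generators
    for beta matrices, segment tables and differential-expression tables
    make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
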