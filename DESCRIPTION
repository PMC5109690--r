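Package: somaticRF
Title: Somatic SNV Calling from Tumor-Normal Pileups with Cost-Sensitive
    Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls somatic single-nucleotide variants from matched
    tumor-normal SAMtools mpileup files using a machine-learning approach
    designed for low-pass sequencing. Candidate sites are screened with
    quality and coverage filters and a Fisher's exact somatic test,
    summarised as a 15-feature vector (quality bias, coverage and variant
    allele frequency, read-position bias, strand bias, and site context),
    and classified by a cost-sensitive Random Forest trained on validated
    true and false positive calls. Includes information-gain feature
    ranking, out-of-bag error estimation, stratified cross-validation,
    ROC/PR/Cohen's-kappa evaluation, VCF output with class probabilities,
    and a matched-pileup simulator with known ground truth for end-to-end
    testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR,
    pROC,
    e1071,
    ranger
Config/testthat/edition: 3
RoxygenNote: 7.3.3
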