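Package: ndcrank
Title: Ranking Nonlinearly Expressed Genes with the Normalized Differential Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Highlights genes whose expression is associated with a binary
    phenotype (e.g. tumor versus adjacent normal tissue) through a nonlinear
    rather than a linear pattern. Implements a maximal information coefficient
    (MIC) estimator specialised to continuous-expression versus binary-label
    pairs via exact dynamic programming over axis partitions, a
    permutation-derived MIC significance threshold, the normalized
    differential correlation (NDC) statistic, and a two-stage gene ranking.
    Includes point-biserial correlation, Welch t and Yates-corrected
    chi-square comparators, a reader for Xena-style genomicMatrix expression
    files, and a synthetic-data generator that plants null, linearly shifted,
    bimodal-nonlinear, and four-level stratified expression patterns with
    ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
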