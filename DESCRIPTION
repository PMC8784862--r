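Package: scDistDE
Title: Individual-Level Differential Expression for Single-Cell RNA-Seq
    via Distribution Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression testing for multi-subject single-cell
    RNA-seq data in which the sampling unit is the individual, not the cell.
    For each gene, the expression distribution of every individual is
    estimated across that individual's cells (negative binomial or
    zero-inflated negative binomial regression adjusting for cell-level
    covariates such as log read depth, or non-parametric alternatives),
    pairwise distances between these distributions are computed
    (Wasserstein-1 or Jensen-Shannon divergence), and association with a
    phenotype is assessed by a covariate-adjusted distance-based pseudo-F
    statistic with a permutation p-value. Includes a zero-inflated negative
    binomial simulator with mean- and variance-shift signal injection, a
    pseudo-bulk negative binomial baseline, and Storey q-value / DE-proportion
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    MASS,
    Matrix,
    stats,
    utils
Suggests:
    glmmTMB,
    optparse,
    parallel,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
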