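Package: fieldexpr
Title: Variance Partitioning and Time-Course Analysis of Field-Grown Plant Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for genome-wide time-series expression of
    plant accessions grown in natural field conditions. Implements principal
    variance components analysis (PVCA) with eigenvalue-weighted aggregation
    of per-component variance fractions, gene-wise factorial ANOVA with
    Benjamini-Hochberg false discovery control, a natural-cubic-spline
    time-course significance test with a permutation null, K-means clustering
    of expression profiles with silhouette-guided selection of the cluster
    number, per-cluster environmental variance attribution and hypergeometric
    gene-set (stress/GO) enrichment, vegetative-stage PCA regressed on weather
    and development covariates with variance-inflation screening,
    extreme-loading gene selection, and template matching of expression
    profiles. A synthetic-data generator emulates the two-accession field
    design (replicated three-day sampling through bolting, autocorrelated
    weather, planted accession/flowering/environment effects and co-expressed
    clusters) and records the ground truth used by the recovery test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    mclust
Config/testthat/edition: 3
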