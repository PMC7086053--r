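Package: landgf
Title: Landscape Genomics with Gradient Forest Turnover and Genomic Offset
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A landscape-genomics inference chain for range-wide SNP panels:
    genotype quality control (heterozygosity, missingness, minor-allele
    frequency and fragment thinning filters), per-population diversity and
    Weir-Cockerham differentiation, ordination summaries (PCA and DAPC),
    Mantel dissection of isolation by distance and by environment,
    genotype-environment outlier scans (PC-based Mahalanobis and
    covariance-standardized rank correlation), gradient-forest turnover
    modeling with R2-weighted cumulative-importance functions, climate-change
    genetic offset, and redundancy-analysis variance partitioning with
    Moran eigenvector maps. Includes a synthetic-landscape simulator that
    generates climates, allele-frequency clines and diploid genotypes with
    tunable isolation by distance and by environment, so the whole chain is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    grDevices,
    geosphere,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    randomForest,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
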