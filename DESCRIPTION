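Package: fairbiome
Title: Fairness-Aware Microbial Signature Discovery Across Unbalanced Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for identifying bacterial 16S rRNA OTU signatures
    of early liver fibrosis across unbalanced multi-country cohorts. Provides a
    synthetic multi-cohort count-table generator with planted differential OTUs
    and cohort batch effects, OTU filtering and normalization (relative
    abundance, cumulative sum scaling with log transform, TF-IDF), alpha and
    beta diversity with permutation tests, sparse PLS discriminant analysis,
    and three cohort-fairness strategies: removal of cohort-correlated
    principal components, l1-penalized spectral clustering of OTU association
    graphs, and fairlet-based cohort-balanced k-median clustering, combined
    into a consensus signature report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    MASS,
    permute,
    randomForest,
    stats,
    utils,
    vegan
Suggests:
    mixOmics,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
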