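Package: phyloTraitML
Title: Phylogenetically Blocked Machine Learning on Microbial Trait Tables
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts a binary genomic feature (such as CRISPR incidence)
    from a text-mined microbial trait table while correcting for shared
    evolutionary history. Converts paired trait confidences into a single
    score, imputes missing scores with an iterative random-forest scheme,
    builds phylogenetically blocked cross-validation folds by partitioning
    patristic distances around medoids, performs forward-selection logistic
    modelling scored by cross-validated Brier error with BIC size selection,
    and fits a Cohen's-kappa-weighted ensemble of random forests trained on
    blocked folds. Includes trait-space ordination, incidence and
    association statistics with exact binomial intervals, and a synthetic
    data generator (Yule trees, Mk-model traits, liability-threshold
    outcomes) so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, ape, randomForest
Suggests: testthat (>= 3.0.0), cluster, e1071, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, Phylogenetics, Clustering, DimensionReduction
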