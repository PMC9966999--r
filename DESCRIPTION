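Package: chemsar
Title: Chemical Space, Scaffold Diversity, Activity Cliffs, and Multiclass
    QSAR for Bioactivity Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for exploring the chemical space of a compound bioactivity
    dataset: curation of IC50/pIC50 activity tables with four-class potency
    binning and random oversampling; drug-likeness descriptors and molecular
    fingerprints computed through Open Babel; per-group exploratory statistics
    with exact Mann-Whitney comparisons; principal-component chemical-space
    projection with a bounding-box applicability domain; Bemis-Murcko scaffold
    decomposition with diversity metrics and scaffold enrichment factors;
    structure-activity similarity (SAS) maps with SALI-based activity-cliff
    detection; and scaffold-stratified multiclass QSAR classification with a
    twelve-algorithm registry, ten-fold cross-validation and Matthews
    correlation metrics. A synthetic molecule generator with known scaffold
    effects and planted activity cliffs supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    methods,
    stats,
    utils,
    e1071,
    kernlab,
    rpart,
    nnet,
    class,
    randomForest,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
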