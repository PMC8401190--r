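Package: slforest
Title: Synthetic-Lethality Inference from CRISPR Dependency Screens via
    All-Relevant Random-Forest Feature Selection
Version: 0.1.0
Authors@R: person("slforest", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Infers candidate synthetic-lethal (SL) gene pairs by explaining
    per-gene CRISPR knockout dependency scores across cancer cell lines with
    pathogenic-mutation and expression features.  A built-in regression random
    forest provides impurity (Gini), bias-corrected impurity and out-of-bag
    permutation importances; a Boruta-style all-relevant selection loop with
    shadow features and binomial/Bonferroni decisions confirms predictive
    features per target gene.  Selected pairs are direction-filtered by
    Pearson correlation, min-max scaled per scoring group, thresholded by
    head/tail-breaks clustering and exported as a directed vulnerability
    network with per-node dependency statistics.  Includes a synthetic-cohort
    generator with planted SL structure for end-to-end validation and a
    command-line pipeline driver.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
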