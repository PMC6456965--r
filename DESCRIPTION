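Package: dopascape
Title: Social-Experience Effects on the Epigenetic Landscape and Sleep of
    Drosophila Dopaminergic Neurons
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for studying how social housing (group-housed
    versus single-housed flies) shifts the joint histone-mark and mRNA
    landscape of a neuron population and its sleep behavior. Implements
    k-means clustering of z-score-normalized between-condition differences
    with BIC/elbow selection of the cluster number and a resampling-based
    cluster-stability metric (maximum percent overlap across repeated runs);
    position-weight-matrix promoter scanning with exact score-distribution
    p-values, cluster-versus-control motif enrichment, and stepwise
    multilinear regression of expression fold change on motif counts; exact
    binomial sign tests, gene-set comparisons and fold-change correlations;
    and sleep-bout scoring of 1-minute activity-monitor traces with daytime
    sleep, delta-sleep between housing groups and a Type III interaction
    ANOVA. A synthetic-data module generates every input with planted ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
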