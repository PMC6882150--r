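Package: dtlclust
Title: Hierarchical Clustering of Duplication-Transfer-Loss Reconciliation Space
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum parsimony reconciliation of a rooted binary gene tree into a
    rooted binary species tree under the duplication-transfer-loss (DTL) event
    model, with the full space of co-optimal reconciliations represented compactly
    as a reconciliation graph. Provides exact counting of maximum parsimony
    reconciliations (MPRs), per-event support values, mean pairwise symmetric
    distance, median representative reconciliations, uniform random sampling and
    exhaustive enumeration of co-optimal solutions, and agglomerative hierarchical
    clustering of MPR space with weighted-average-support or
    weighted-average-distance linkage, including improvement diagnostics for
    choosing the number of clusters. A command-line interface covers the
    reconcile/cluster/report workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Phylogenetics, Clustering, Software
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'trees.R'
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'dp.R'
    'oracle.R'
    'graphops.R'
    'clustering.R'
    'fixtures.R'
    'report.R'
    'cli.R'
    'dtlclust-package.R'
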