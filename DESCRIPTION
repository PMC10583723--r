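Package: batchalloc
Title: Batch Allocation for Observational Studies with Sequential Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Allocates a fixed cohort with one nominal treatment variable to
    processing batches so that treatment and batch effects remain estimable
    with balanced precision. Implements a stochastic batch-allocation (SBA)
    heuristic driven by the treatment concurrence matrix, a random binary
    allocation (RBA) baseline, exact integer D-criterion scoring of the
    intercept + treatment + batch model, an exhaustive optimizer for small
    instances, a multi-run evaluation harness, and post-allocation
    randomization of batch order, subject assignment, and within-batch
    processing order.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
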