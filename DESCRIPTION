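Package: ibdcoal
Title: Identity-by-Descent Detection and Dating with a Coalescent Hidden Markov Model
Version: 0.1.0
Authors@R:
    person("ibdcoal", "developers", email = "ibdcoal@example.org", role = c("aut", "cre"))
Description: Detects pairwise identity-by-descent (IBD) segments in phased
    haplotype panels using a two-stage procedure: a windowed genotype-hashing
    identification step with recursive bin diversification and phasing-error
    tolerance, followed by verification with a coalescent hidden Markov model
    over discretized time-to-most-recent-common-ancestor (TMRCA) intervals.
    Verified segments carry an IBD quality score (posterior probability of
    coalescence within a user-chosen time threshold) and a maximum a
    posteriori age estimate. Includes a discrete-generation Wright-Fisher
    coalescent simulator with ground-truth TMRCA paths and SNP-array
    ascertainment, site-level precision/recall evaluation, a
    density-of-recent-coalescence selection scan with a Gamma null model,
    IBD-based effective population size estimation, cousin-sharing
    expectations, k-nearest-neighbour birth-location prediction, sparse
    average-linkage clustering, and loss-of-function segment burden
    association testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
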