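Package: pprlink
Title: Probabilistic Privacy-Preserving Record Linkage with Bloom Filters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probabilistic record linkage of privacy-preserved
    (encrypted) person records. Identifying fields are encoded into field-level
    Bloom filters or keyed hash tokens, candidate pairs are formed by blocking,
    and pairs are scored under the Fellegi-Sunter model with Winkler-style
    partial agreement weights on Sorensen-Dice similarities. Match parameters
    (m- and u-probabilities, extended with explicit missing-value states) are
    estimated directly on the encrypted data with an expectation-maximisation
    algorithm; u-probabilities can alternatively be estimated from unblocked
    value frequencies. An optimal decision threshold is estimated from the
    predicted precision/recall/F-measure over the full field-state space.
    Includes a synthetic person-record generator with configurable duplicate
    structure and error injection, and evaluation utilities against a truth
    set.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
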