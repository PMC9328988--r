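Package: wbbn
Title: Weighted Bayesian Belief Networks for Discretized Clinical Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted Bayesian belief network classifiers for
    discretized categorical clinical datasets. Attribute-value pairs are
    ranked and weighted by their co-occurrence with the positive class,
    weighted association rules are mined in two-attribute, multi-attribute
    and class-label modes, strong rules are selected by weighted Bayes
    confidence and lift, and a Bayesian network is learned over the
    strong-rule attributes with K2 structure search and Dirichlet-smoothed
    conditional probability tables. Includes readers for the LUCS-KDD
    item-number format and discretization of raw CSV tables, a synthetic
    data generator with planted network structure for end-to-end testing,
    an evaluation harness with stratified holdout and threshold sweeps,
    and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
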