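Package: autapodate
Title: Autapomorphies, Ascertainment Bias and Bayesian Tip-Dating of Fossil Morphologies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Likelihood machinery for discrete morphological characters under
    the symmetric Markov-k (Mk) model with ascertainment-bias corrections for
    unobservable character classes: variable-only (Mkv) and
    parsimony-informative-only (Mk-parsinf) conditioning, including exact
    integer counting and enumeration of the unobservable site patterns that
    the parsimony-informative correction must evaluate.  Provides a
    birth-death serial-sampling tree simulator, Mk character simulation on
    dated trees, a simplified fixed-topology Bayesian tip-dating MCMC with
    strict and uncorrelated-lognormal relaxed clocks, parsimony clocklikeness
    diagnostics, and an experiment pipeline measuring how excluding
    autapomorphies biases inferred branch durations on clocklike versus
    non-clock data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    coda,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
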