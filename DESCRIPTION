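Package: icdl
Title: Intervener Complexity and Dependency Length Analysis of Dependency Treebanks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for corpus studies of word-order constraints in dependency
    treebanks. Computes per-dependency length (number of intervening words) and
    intervener complexity (number of intervening syntactic heads), generates six
    constrained random baselines (uniform random tree structures via Pruefer
    codes and random linear arrangements, optionally rejection-sampled to match
    the real tree's crossing count and its dependency-length or
    intervener-complexity multiset), and fits linear mixed-effects interaction
    models contrasting real and baseline trees as a function of sentence length.
    Includes a CoNLL-U reader/writer, a synthetic treebank generator with
    controllable word-order policies for end-to-end validation, and a pipeline
    that produces estimate tables, hypothesis verdicts and distribution
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
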