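Package: chemner
Title: Chemical Named-Entity Recognition with a Linear-Chain CRF and a
    Probabilistic Ensemble Combiner
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating chemical entity mentions (names and
    formulas) in scientific abstracts.  Provides a first-order
    linear-chain conditional random field tagger with a
    chemistry-oriented feature battery (Soundex phonetic codes,
    word-embedding cluster identifiers, token-shape predicates,
    character n-grams and gazetteer lookups), a probabilistic ensemble
    combiner that fuses span predictions from several extractors into
    calibrated per-entity confidences via conditional-precision
    estimation, exact-span evaluation, a tokenizer-boundary benchmark,
    and a seeded synthetic-corpus generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
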