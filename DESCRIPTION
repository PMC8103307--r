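Package: famhx
Title: Family History Information Extraction from Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end extraction of family history information from
    free-text clinical notes: identification of family member, observation
    (disease) and living-status entity mentions with a hybrid of rule-based
    matching and an ensemble of bidirectional recurrent BIO sequence
    taggers; extraction of family member-living status and family
    member-observation relations with online-gradient-descent linear
    classifiers over hashed lexical window features; heuristic attribute
    classification (kinship normalization, family side, living-status
    scoring, ConText-style negation); shared-task style micro-averaged
    evaluation with partial observation matching and attribute ablations;
    and a deterministic synthetic-corpus generator with gold
    character-offset annotations for development and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
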