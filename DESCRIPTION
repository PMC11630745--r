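Package: connspeech
Title: Quantitative Connected-Speech Analysis and Diagnostic Word Checklists
    for Progressive Aphasia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for picture-description connected speech in
    progressive aphasias and related motor disorders (svPPA, lvPPA, nfvPPA,
    PSP, CBS). Parses disfluency-annotated transcripts, computes thirteen
    speech-fluency measures (token/type counts for words, bigrams and
    trigrams, type-to-token ratios, words per minute, function/content
    proportion, combination ratio), annotates content words with
    psycholinguistic norms, runs varimax-rotated principal component analyses
    with Kaiser-Meyer-Olkin adequacy and scree-based component selection,
    performs fixed-edge quartile distribution analyses with group difference
    maps, and derives picture-specific 15-word diagnostic checklists by
    pairwise L1-penalized logistic regression with hierarchical k-fold and
    out-of-sample validation. Includes a synthetic-cohort generator that
    reproduces the statistical structure the analyses assume, so every stage
    is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
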