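Package: taglm
Title: Bootstrap Discovery of Lexicogrammatical Discriminators from Tagged
    Speech Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies lexicogrammatical features whose per-word usage
    rates discriminate between two diagnostic groups of speakers.
    Speaker-by-tag count tables are normalized by each speaker's total
    word production, a ridge-penalized logistic regression ("Tag Linear
    Model") is refit over bootstrap resamples of speakers, and per-tag
    coefficient moments yield normal-approximation p-values used to
    select discriminators at a chosen significance level.  Selected tags
    can be filtered by structural level (clause/phrase versus smaller
    units) and mapped onto cognitive-functional domains.  A synthetic
    corpus generator with Poisson or negative-binomial tag counts
    provides fully reproducible test beds, including a preset that
    mirrors the effect-sign pattern of the published discriminator
    table for autism spectrum disorder versus non-ASD speech.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
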