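Package: semprosody
Title: Semantic Prosody, Embedding Valence Bias, and Evaluative-Priming Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative machinery for studying semantic prosody: corpus
    collocation extraction with mutual-information filtering and
    frequency-weighted collocate-valence scoring; word-embedding valence
    bias as a Hedges-g standardized difference of cosine similarities to
    positive versus negative attribute sets; trial-level evaluative-priming
    reaction-time preprocessing, repeated-measures ANOVA and simple
    effects; effect-size conversions and noncentral-F sensitivity power
    analysis; and synthetic-data generators (corpora with planted
    collocations, embedding spaces with planted bias, lognormal
    reaction-time data with planted congruity effects) so the full
    pipeline is testable without licensed corpora, pretrained vectors, or
    human participants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
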