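Package: sentibook
Title: Vector-Space-Model Sentiment Analysis for Book-Length Texts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate, embedding-based sentiment analysis for whole books.
    Scores every content word (nouns, verbs, adjectives, adverbs) of a text by
    its affective-aesthetic potential (AAP) -- the mean cosine similarity to a
    set of positive label words minus the mean cosine similarity to a set of
    negative label words -- together with six discrete-emotion scores (cosine
    to single emotion labels), aggregates them to sentence, book and corpus
    profiles including the positive/negative word ratio (PNR), builds smoothed
    emotional narrative arcs and AAP histograms, extracts the most affectively
    extreme word types, and cross-validates computed AAP against human valence
    ratings with linear and four-parameter-logistic fits. Includes a fully
    deterministic synthetic-data generator (embedding space with a planted
    valence axis, corpora with a controllable positivity bias, ratings from a
    logistic response curve) so the entire pipeline is testable end to end
    without external corpora or pretrained embeddings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
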