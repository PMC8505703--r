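Package: negindex
Title: Lexicon-Based Negative Perception Index for Tweet Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lexicon-based surveillance of negative sentiment in
    social-media text streams. Counts occurrences of a curated negative-word
    lexicon in daily tweet corpora, computes the daily negative frequency
    index I(d) = N(d)/T(d) (negative-word occurrences per tweet), and
    characterises its temporal behaviour: rolling means, windowed linear
    trend fits with confidence intervals, plateau/band checks, permutation
    contrasts between date windows, and correlation with external daily
    series such as deaths or vaccination coverage. Includes a seeded
    synthetic tweet-corpus generator with known ground truth so the whole
    pipeline can be validated by parameter recovery without platform access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
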