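Package: whalesong
Title: Humpback Whale Song Evolution, Similarity and Complexity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cultural evolution in humpback whale
    (Megaptera novaeangliae) song from symbolic transcriptions. Implements
    token-level Levenshtein edit distance and the length-normalised
    Levenshtein Distance Similarity Index (LSI), set-median sequences,
    Dice's Similarity Index on phrase-type inventories, UPGMA clustering
    with cophenetic correlation and multiscale-bootstrap (AU/BP) node
    supports, a PCA-based song-complexity score with a year-effect linear
    model, and first-order theme-transition matrices with an entropy-based
    stereotypy summary. Ships a transcription of a three-year Okinawa
    (2011-2013) song corpus and a seeded synthetic-corpus generator with a
    truth record for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
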