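Package: ethochunk
Title: Blinded Randomized Chunk Sampling and Scoring of Behavior Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for blinded, stratified-random scoring of long
    behavior recordings. Partitions a recording into contiguous Pieces,
    draws non-overlapping fixed-duration Chunks from each Piece with a
    seeded, reproducible stream, and pools chunks across recordings into a
    blinded, randomly ordered presentation schedule. Provides an ethogram
    data model with validated CSV round-trip for interval and point
    behavioral events, chunk-level presence/absence scoring, whole-video
    maternal-behavior measures (pup-retrieval latencies with censoring,
    ordinal nest score), exact and normal-approximation Wilcoxon rank-sum
    group comparisons with median/IQR summaries, a synthetic dam-behavior
    generator with ground-truth records for end-to-end validation, and
    small acquisition-side planning utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
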