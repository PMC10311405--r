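Package: squigglemap
Title: Real-Time Mapping of Raw Nanopore Signals by Quantized Event Hashing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps raw nanopore current signals to a reference genome without
    basecalling, in a streaming fashion suitable for adaptive sampling
    (Read Until). Reference k-mers are converted to expected event levels
    through a pore model, z-score normalized, quantized to a handful of
    bits taken from their single-precision encoding, packed over several
    consecutive events and hashed into a 32-bit seed table; raw reads are
    segmented into events by multi-window Welch t-tests, processed chunk by
    chunk, and placed by colinear anchor chaining with an acceptance rule on
    the best and second-best chains. Includes a relative-abundance monitor
    that stops a sequencing run once estimates converge (Sequence Until),
    a raw-signal simulator with ground truth for offline evaluation, and
    PAF input/output with mapping-accuracy summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
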