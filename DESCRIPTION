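Package: memalign
Title: Anchor-Based Vertical-Division Multiple Nucleotide Sequence Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multiple alignment of long, similar nucleotide sequences by
    vertical division. Maximal exact matches (MEMs) shared across the input
    are enumerated from a generalized suffix array and LCP array, filtered to
    a maximum-size colinear subset, extended into partial chains with local
    alignment, and used to cut the sequences into segments that are aligned
    independently and re-assembled. Uncovered fragments are attached by banded
    sequence-profile alignment and the concatenated result is refined at the
    junctions. Includes alignment quality scoring (Q, TC, sum-of-pairs) and a
    simulator for homologous sequence families with a known true alignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    seqinr,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
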