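Package: clgbo
Title: DNA Storage Coding Sets via a Cauchy-Levy Gradient-Based Optimizer
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Constructs sets of fixed-length DNA codewords for use as primer
    and address libraries in DNA data storage. Words are selected under
    combinatorial constraints: pairwise Hamming distance, balanced GC
    content, homopolymer exclusion (no-runlength), and a tandem-repeat
    ("non-adjacent subsequence") constraint that suppresses polymerase
    slippage. Sets are grown incrementally with CLGBO, a gradient-based
    population optimizer enhanced with Cauchy and Levy mutation, with the
    hot loop in C++; small instances are certified optimal by exhaustive
    enumeration plus exact branch-and-bound maximum-clique search. Includes
    a benchmark-function harness for the optimizer and nearest-neighbor
    melting-temperature analysis of constructed sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
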