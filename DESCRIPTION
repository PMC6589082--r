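Package: fuzzydemux
Title: Declarative Fuzzy Template Matching for Demultiplexing and
    Trimming Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pattern-matching engine for line-oriented sequencing data
    (FASTQ and any other line-delimited text format) driven by a small
    declarative template language.  Templates arrange fuzzy patterns
    (approximate matches of barcodes or adapters under Hamming,
    Levenshtein, or restricted Damerau-Levenshtein distance),
    fixed-length wildcards, and interval-length wildcards, and bind
    match statistics to variables that later patterns and output file
    names can reference.  Matching uses banded edit-distance dynamic
    programming with Ukkonen's cutoff, a bit-parallel Hamming searcher,
    n-gram pre-elimination of subpatterns, and a prefix-sum dynamic
    program for chains of interval-length wildcards, tied together by a
    greedy chunked line matcher.  Includes streaming demultiplexing with
    batched parallel processing, a command-line interface, a synthetic
    read simulator with ground truth, and a difference metric for
    scoring demultiplexing output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    optparse,
    parallel,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
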