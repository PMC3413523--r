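Package: msamerge
Title: Consensus Multiple Sequence Alignments by Column-Graph Dynamic
    Programming
Version: 0.1.0
Authors@R:
    person("msamerge", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Merges two or more multiple sequence alignments of the same
    sequences into a single consensus alignment. Alignment columns are
    encoded as tuples of cumulative residue counts and assembled into a
    weighted directed acyclic graph; a dynamic program selects the path
    that favours columns shared by many input alignments, and each
    consensus column receives a support score equal to the fraction of
    inputs containing it. Also provides letter-pair precision, recall
    (Q-score) and F-score evaluation of alignments against a reference,
    per-column precision, a power-law model relating column support to
    expected precision, score-based column filtering, a synthetic
    alignment generator for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
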