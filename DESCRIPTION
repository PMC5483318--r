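Package: starmsa
Title: Center-Star Multiple Alignment of Highly Similar DNA/RNA Sequences
Version: 0.1.0
Authors@R: person("starmsa", "developers", email = "starmsa@example.org",
    role = c("aut", "cre"))
Description: Center-star multiple sequence alignment for large sets of highly
    similar DNA/RNA sequences. Provides linear-time center-sequence selection
    via 2-bit encoding of disjoint 8-mer segments and a 2^16-slot occurrence
    table, full and banded (k-band) Needleman-Wunsch pairwise alignment with a
    deterministic backtrace, gap-profile merging of the pairwise results into
    the final alignment, sum-of-pairs scoring, a measured-throughput two-pool
    workload partitioner for parallel execution, a sequence-evolution
    simulator for highly similar datasets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    parallel,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
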