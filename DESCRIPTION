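Package: hapflat
Title: Haplotype-Constrained Flattening of Variation Graphs for Linear Read Alignment
Version: 0.1.0
Authors@R:
    person("hapflat", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds haplotype-annotated population (variation) graphs from a
    reference genome plus phased VCF calls, or loads them from GFA1, and
    flattens them into an edge-free set of sequences (a null graph) that
    covers exactly the k-length substrings of the encoded haplotypes.  The
    emitted FASTA can be indexed by any linear read aligner (e.g. BWA);
    alignments against it are then projected back onto paths through the
    original graph via per-base provenance intervals.  Includes a seeded
    population simulator with truth-tracked reads for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
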