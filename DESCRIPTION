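Package: structmapr
Title: Bidirectional Coordinate Mapping Between Genome, Protein Isoforms
    and 3D Structure Residues
Version: 0.1.0
Authors@R:
    person("structmapr", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Maps positions bidirectionally across three coordinate systems:
    genomic coordinates, protein sequence positions (splice isoforms and a
    canonical reference), and structure residue numbering (chain, author
    residue number, insertion code).  Implements codon-aware transcript
    arithmetic with strand and phase handling, splice-isoform to canonical
    alignment projection, SIFTS-style residue-level sequence/structure
    mapping, provenance-tagged annotation tracks on the canonical sequence
    with JSON serialization, and BED export of structure coverage onto the
    genome.  Ships a deterministic synthetic-fixture generator with
    per-base ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
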