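Package: syntanchor
Title: Scaffold Anchoring, Synteny-Based Gene-Loss Detection, and Dollo
    Loss Mapping for Draft Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of a draft, scaffold-level
    genome assembly against the chromosome-level assembly of a related
    species. Scaffolds are anchored to reference chromosomes by a
    majority vote over per-gene best BLAST hits and classified as
    conserved or rearranged by a strict better-than-50 percent rule;
    anchored scaffolds are ordered and oriented into hypothetical
    chromosomes emitted as AGP 2.1. Reference genes missing from the
    query are called as syntenic losses when their conserved flanking
    genes remain adjacent on one query scaffold, and gene losses are
    assigned to branches of a rooted species tree by Dollo parsimony
    on a presence/pseudogene/absence matrix. A genome-evolution
    simulator (inter-chromosomal translocations, chromosome fission,
    gene loss and pseudogenization, scaffold fragmentation, noisy hit
    tables) provides ground truth so every stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
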