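Package: karyorec
Title: Comparative Gene Maps and Ancestral Karyotype Reconstruction for Marsupials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative cytogenetic mapping and ancestral karyotype
    inference. Detects conserved synteny blocks between two genomes from ortholog
    position tables and selects FISH probe targets at block ends; assembles and
    accounts for species gene maps, flagging genes whose observed chromosome
    contradicts expectation; delineates oriented conserved segments between two
    gene maps and assigns chromosome-painting segment labels with boundary
    ambiguity calls; reconstructs ancestral karyotypes at internal nodes of a
    species tree from signed segment arrangements by adjacency parsimony with
    outgroup arbitration, assembles contiguous ancestral regions (CARs), computes
    diploid numbers and double-cut-and-join (DCJ) rearrangement distances; and
    simulates signed-genome evolution (inversion, fission, fusion, translocation)
    along a tree so every stage can be validated against known histories.
    Includes fixtures encoding published marsupial conserved-segment arrangements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
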