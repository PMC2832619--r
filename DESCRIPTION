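Package: ceafam
Title: Molecular Evolution Toolkit for Immunoreceptor Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the molecular evolution of
    CEACAM-like immunoreceptor gene families: immunoreceptor
    tyrosine-based motif (ITIM/ITSM/ITAM) classification of cytoplasmic
    domains, gene/pseudogene delineation from exon structure,
    Nei-Gojobori synonymous/nonsynonymous substitution estimation with
    per-codon substitution profiles and conserved-region delineation,
    neighbour-joining phylogenetics with bootstrap support, detection of
    gene-conversion tracts between paralog pairs by low-synonymous-
    divergence runs with a permutation null, and percent-identity
    segment computation between gene loci.  A seedable gene-family
    simulator with known ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
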