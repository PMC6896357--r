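Package: nachrex
Title: Comparative Genomics of Nicotinic Acetylcholine Receptor Gene-Family Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for studying lineage-specific expansion of
    nicotinic acetylcholine receptor (nAChR) genes and similar gene families.
    Provides domain-architecture classification of receptor candidates,
    exon-intron structure analysis with retrogene identification, normalized
    bitscore (H-score) hierarchical clustering into gene families,
    neighbor-joining trees with bootstrap support, Wagner-parsimony
    reconstruction of ancestral family sizes on a species tree, tandem-array
    detection from genomic coordinates, and RPKM-based expression
    classification. Includes a synthetic genome-cohort simulator with known
    evolutionary events (tandem duplication, retroposition, intron gain,
    gene loss, pseudogenization) for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
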