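Package: lactopan
Title: Pangenome, Core-SNP Phylogeny and Gene-Trait Matching for
    Bacterial Strain Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for closed bacterial species such
    as Lactococcus lactis. Builds orthologous groups from all-vs-all protein
    similarity with Markov clustering, derives a tri-state (present /
    pseudogene / absent) presence matrix, estimates pan- and core-genome
    rarefaction curves with permutation spread, concatenates variable sites
    of single-copy core genes into a supermatrix for neighbor-joining
    phylogeny with outgroup re-rooting, classifies plasmid contigs from
    relative read coverage, and ranks orthologous groups that discriminate
    binary strain traits (subspecies, isolation niche) with a
    pseudogene-neutral score, permutation p-values and leave-one-out
    prediction. Ships a seeded simulator that plants a known phylogeny,
    clade- and niche-specific marker genes, pseudogenization and plasmid
    contigs so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    Matrix,
    phangorn,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
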