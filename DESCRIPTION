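Package: panevo
Title: Bacterial Pan-Genome Structure, Openness and Phylogenetic Incongruence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for bacterial pan-genomes built from
    genome-tagged gene sequences: ortholog clustering by global-alignment
    single linkage, core/softcore/shell/cloud partitioning, pan- and
    core-genome accumulation curves with Heaps'-law openness fitting,
    average nucleotide identity (ANI) matrices and species clustering,
    per-gene neighbor-joining trees, tree-distance ranking of
    representative genes (Robinson-Foulds, matching-split, quartet),
    consensus-based SNP calling, a best-match plus tree-incongruence
    screen for horizontal gene transfer, and accessory-genome category
    enrichment. Includes a multi-species pan-genome simulator with known
    ground truth (species tree, gene-family carrier sets, planted
    transfers) for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    mclust,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
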