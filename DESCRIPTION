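Package: bqpipe
Title: Comparative Genomics of Genome Reduction in Photosynthetic Picoeukaryotes
Version: 0.1.0
Authors@R:
    person("bqpipe", "developers", email = "bqpipe@example.org", role = c("aut", "cre"))
Description: Tools for studying gene loss and genome reduction across
    unicellular algal genomes. Parses OrthoFinder-style orthogroup tables
    and computes pangenome partitions (core/shared/unique), propagates
    KEGG Orthology annotations by orthogroup consensus, builds
    compound-level metabolic networks via KO-to-reaction-to-compound
    mapping, compares networks with Jaccard, weighted Jaccard, Canberra
    and Adkins-Canberra distances, builds neighbor-joining network trees
    and measures their split-based congruence with a species tree, screens
    functional-category gene counts against proteome size using
    phylogenetic independent contrasts, and evaluates the
    proteomic-constraint relation between mutation rate and genome
    information content. Ships a gene-content simulator (Poisson loss
    along a phylogeny with lineage- and category-specific rates) so the
    whole pipeline is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    vegan,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
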