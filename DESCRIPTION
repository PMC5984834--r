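Package: gcfkit
Title: Gene Cluster Family Analysis for Comparative Bacterial Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Groups biosynthetic gene clusters (BGCs) into gene cluster
    families (GCFs) by explicit architecture/function/identity/module-position
    criteria and by Pfam-domain similarity networking (Jaccard and domain
    duplication indices), profiles GCF presence/absence against strain
    phylogeny with Dice/UPGMA clustering, quantifies GCF richness by
    sample-based rarefaction, delimits genera by the percentage of conserved
    proteins (POCP), and maps BGC positions relative to the replication origin
    on circular genomes. Includes a synthetic-genome generator with planted
    family structure so every stage of the pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    phangorn,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
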