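Package: polysnp
Title: Sub-Genome-Aware SNP Discovery in Allopolyploid Amplicon Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based pipeline for discovering allelic SNPs within the
    sub-genomes of allopolyploid species from barcoded amplicon resequencing
    data. Multiplexed reads are demultiplexed by barcode, assigned to amplicon
    templates, and decomposed by stringent overlap clustering into putative
    sub-genome consensus contigs. Homoeologous sequence variants (HSVs, fixed
    differences between sub-genomes) are separated from allelic SNPs
    (segregating within a sub-genome) and from variants diagnostic between
    morphotype panels. SNP-bearing haplotypes are attributed to progenitor
    sub-genomes with neighbour-joining trees, dosage-based co-dominant
    genotypes are called from two-channel intensity ratios, and SNP-based
    diversity is summarised with Dice similarities and UPGMA phenograms. A
    synthetic allohexaploid data generator with full ground truth makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vcfR,
    optparse
Config/testthat/edition: 3
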