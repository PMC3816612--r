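Package: ESTevo
Title: EST-Based Marker Mining, Whole-Genome-Duplication Dating and
    Phylogenetics for Radish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative-genomic analysis of expressed sequence
    tag (EST) collections, modelled on the radish (Raphanus) EST resource:
    N-fraction quality filtering and unigene assembly summaries,
    microsatellite (SSR) mining with compound-motif merging, multi-accession
    SNP calling with transition/transversion/indel classification,
    synonymous-substitution (Ks) distributions of reciprocal-best paralog
    pairs with kernel-density peak detection and fossil-calibrated
    whole-genome-duplication dating (T = Ks/r), and neighbor-joining
    phylogenies of accessions from complete-information SNP genotype
    matrices with bootstrap support. A synthetic-data generator plants SSRs,
    tree-structured SNPs and duplicated gene families at controlled
    synonymous divergence so every stage can be validated against known
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
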