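Package: plastomeDiag
Title: Comparative Plastome Analysis: Quadripartite Structure, Diagnostic
    Nucleotides and Codon Usage
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of chloroplast genomes
    (plastomes) at shallow evolutionary scales. Detects the quadripartite
    structure (LSC, SSC and the inverted repeats) by exact inverted-repeat
    search, characterises junction-site gene context, computes sliding-window
    tracks of SNPs, indels, nucleotide diversity (pi) and diagnostic
    nucleotides ("diagnostides") over grouped multiple alignments to rank
    candidate superbarcode regions, and computes relative synonymous codon
    usage (RSCU) with hierarchical clustering, dendrogram-versus-phylogeny
    comparison and tribe-level rank tests. Includes generators for synthetic
    plastomes, grouped alignments with planted variation, and codon-biased
    coding sets, so every stage can be validated against planted ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Genetics, Phylogenetics, SequenceMatching, Alignment,
    ComparativeGenomics
RoxygenNote: 7.3.3
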