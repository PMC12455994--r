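Package: endoreg
Title: Nucleotide Composition, Regulatory Motifs, and Gene Expression in
    Endosymbiont Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit linking gene nucleotide composition to gene
    expression in reduced endosymbiont genomes such as Wolbachia.
    Implements per-gene composition metrics (base percentages under the
    gene-strand convention, Codon Bias Index, Wright's effective number of
    codons), a cross-study log2 relative-abundance normalization with
    quantile conversion, per-sample Spearman correlation scans with
    per-strain Bonferroni correction, IUPAC degenerate motif scanning of
    upstream regions with a one-mismatch budget and cross-genome
    conservation summaries, generalized additive mixed models testing
    whether a focal methyltransferase gene (midA) modulates
    composition-expression correlations, profiling of adenine-extreme
    genes by COG category, and gene-tree/species-tree topological
    concordance. A seeded synthetic-data generator emulates the study
    design (AT-rich genomes with planted motifs, expression driven by
    composition, gene trees with controlled discordance) so that every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    ape,
    phangorn,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
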