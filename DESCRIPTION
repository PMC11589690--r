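Package: neoXY
Title: Detection and Characterization of Neo-Sex Chromosomes from
    Population Resequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering and characterizing neo-sex chromosomes
    from male/female population resequencing data. Implements a windowed
    coverage and heterozygosity scan with confidence-interval outlier
    flagging and region calling, a hard-filter cascade for genotype calls,
    clustering of phased haplotypes to separate X- and Y-linked
    (gametologous) haplotypes with haploid regenotyping, codon-aware
    alignment and Nei-Gojobori dN/dS estimation for gametolog pairs,
    ORF-disruption (pseudogene) scoring, whole-genome alignment block
    filtering and rearrangement classification, and sex-differential
    repeat enrichment and divergence landscapes. A ground-truthed
    synthetic neo-XY population simulator makes every stage testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
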