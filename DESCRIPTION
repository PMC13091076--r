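Package: piliscan
Title: Comparative Genomics of Type IV Pilus Loci in Bifidobacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies tight-adherence (Tad/T4cP) and type IVa
    pilus (T4aP) loci in annotated bacterial genomes, screens genes for
    horizontal-transfer signatures from codon usage bias (RSCU deviation,
    effective number of codons, codon adaptation index) and GC content using
    per-genome dynamic percentile thresholds, clusters orthologs across
    genomes with Markov clustering to build a single-copy core genome and a
    neighbor-joining phylogeny, measures conservation of the genes flanking
    detected loci, and renders genetic maps of the loci as SVG. Includes a
    synthetic-genome simulator with ground-truth manifests for end-to-end
    validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    Matrix,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
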