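Package: wildcomp
Title: Comparative Genomics of a Wild and a Cultivated Genotype: Synteny,
    Gene Presence/Absence, Molecular Dating, SNV Landscapes and
    Tissue-Specific Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable implementation of the comparative layer
    of a two-genotype genome comparison, as applied to wild versus
    cultivated barley: seeded local alignment with identity and coverage
    reporting, all-vs-all homologous gene pair detection, syntenic block
    chaining from gene orders, presence/absence (genotype-specific) gene
    classification with read-coverage confirmation, Nei-Gojobori (1986)
    Ka/Ks and Jukes-Cantor molecular-clock dating of orthologs and LTR
    retrotransposons, pileup SNV calling with windowed density profiling,
    and tissue-specific expression classification from count matrices.
    Ships a deterministic two-genotype genome simulator with planted
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    SummarizedExperiment,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
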