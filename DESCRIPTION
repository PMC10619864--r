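Package: mossheat
Title: Duplicated-Gene Modes, Heat-Stress Expression Islands and Hub Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analyses for a heat-stress transcriptome time series
    on a compact plant genome: classification of duplicated genes into
    whole-genome, tandem, proximal, transposed and dispersed duplicates from
    homolog pairs and collinear blocks; Nei-Gojobori (1986) Ka/Ks estimation
    on codon alignments with a Ks saturation filter; TPM normalisation and
    fold-change/p-value differential-expression calls across staged
    contrasts; detection of physical "islands" of co-localised upregulated
    genes by a 50-kb window rule; module-eigengene hub-gene scoring with
    module-membership and gene-significance thresholds and adjacent-hub
    grouping; and an assembly contamination screen based on interval-union
    alignment coverage per query. A seeded synthetic-data generator plants
    known duplication events, expression effects, islands, modules and
    contaminant scaffolds so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
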