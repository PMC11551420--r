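Package: TFdirect
Title: Direct Target Gene Inference from ChIP-Seq Binding and Tissue-Contrast Coexpression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genes directly targeted by a transcription factor by
    intersecting reproducible ChIP-Seq peaks (assigned to genes through a
    1 kb upstream-of-TSS through gene-body window) with genes coexpressed
    with the factor across tissue contrasts, and analyses the cis-regulatory
    grammar of the resulting binding sites: degenerate IUPAC motif
    enrichment against matched random-region and random-gene-set nulls,
    positional motif and peak profiles, genomic-feature annotation,
    hypergeometric gene-set overlaps, and two-factor peak co-localization.
    Includes TMM normalization with a conditional negative-binomial exact
    test for the tissue contrasts, ChIP library QC (nonredundant fraction,
    strand cross-correlation), and a synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'TFdirect-package.R'
    'gene-models.R'
    'genome-io.R'
    'motifs.R'
    'simulate.R'
    'expression.R'
    'peaks.R'
    'utils.R'
    'set-stats.R'
    'motif-enrichment.R'
    'pipeline.R'
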