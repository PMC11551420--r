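#' @include AllClasses.R
NULL

#' Accessors for GeneModels
#'
#' `geneIds()` returns the gene identifiers; `geneRanges()` the per-gene
#' `GRanges`; `tss()`/`tts()` the strand-aware transcription start/termination
#' positions (named integer vectors); `exonRanges()`, `utr5Ranges()` and
#' `utr3Ranges()` the sub-feature `GRangesList`s; `intronRanges()` derives
#' introns as gaps between consecutive exons.
#'
#' @param x a [GeneModels-class] object.
#' @return See description; positions are 1-based.
#' @name GeneModels-accessors
#' @aliases geneIds geneRanges tss tts exonRanges utr5Ranges utr3Ranges intronRanges
NULL

#' @rdname GeneModels-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModels-accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneModels-accessors
#' @export
setGeneric("tss", function(x) standardGeneric("tss"))

#' @rdname GeneModels-accessors
#' @export
setGeneric("tts", function(x) standardGeneric("tts"))

#' @rdname GeneModels-accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname GeneModels-accessors
#' @export
setGeneric("utr5Ranges", function(x) standardGeneric("utr5Ranges"))

#' @rdname GeneModels-accessors
#' @export
setGeneric("utr3Ranges", function(x) standardGeneric("utr3Ranges"))

#' @rdname GeneModels-accessors
#' @export
setGeneric("intronRanges", function(x) standardGeneric("intronRanges"))

#' @rdname SyntheticTruth-accessors
#' @export
setGeneric("boundGenes", function(x) standardGeneric("boundGenes"))

#' Accessors for SyntheticTruth
#'
#' Planted truth sets of a synthetic study: `boundGenes()`,
#' `coexpressedGenes()`, `dtGenes()` (the planted direct targets),
#' `motifBearingSites()` and `tfbOffsets()`.
#'
#' @param x a [SyntheticTruth-class] object.
#' @name SyntheticTruth-accessors
#' @aliases boundGenes coexpressedGenes dtGenes motifBearingSites tfbOffsets
#' @export
setGeneric("coexpressedGenes", function(x) standardGeneric("coexpressedGenes"))

#' @rdname SyntheticTruth-accessors
#' @export
setGeneric("dtGenes", function(x) standardGeneric("dtGenes"))

#' @rdname SyntheticTruth-accessors
#' @export
setGeneric("motifBearingSites", function(x) standardGeneric("motifBearingSites"))

#' @rdname SyntheticTruth-accessors
#' @export
setGeneric("tfbOffsets", function(x) standardGeneric("tfbOffsets"))

#' @rdname IUPACMotif-methods
#' @export
setGeneric("motifName", function(x) standardGeneric("motifName"))

#' Accessors for IUPACMotif
#'
#' `motifName()` and `motifPattern()` return the motif's name and consensus
#' string; `motifLength()` its length in bases.
#'
#' @param x an [IUPACMotif-class] object.
#' @name IUPACMotif-methods
#' @aliases motifName motifPattern motifLength
#' @export
setGeneric("motifPattern", function(x) standardGeneric("motifPattern"))

#' @rdname IUPACMotif-methods
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))
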