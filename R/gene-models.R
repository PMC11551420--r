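#' @include AllGenerics.R
NULL

#' Construct a GeneModels object
#'
#' @param genes `GRanges` with `mcols()$gene_id`.
#' @param exons,utr5,utr3 `GRangesList`s named by gene id, parallel to
#'   `genes`.  When `exons` is missing every gene becomes single-exon
#'   spanning its full range with empty UTRs.
#' @return A validated [GeneModels-class] object.
#' @export
GeneModels <- function(genes, exons = NULL, utr5 = NULL, utr3 = NULL) {
  ids <- as.character(mcols(genes)$gene_id)
  emptyGL <- function() {
    gl <- GRangesList(rep(list(GRanges()), length(genes)))
    names(gl) <- ids
    gl
  }
  if (is.null(exons)) {
    exons <- GenomicRanges::split(GenomicRanges::granges(genes),
                                  factor(ids, levels = ids))
  }
  if (is.null(utr5)) utr5 <- emptyGL()
  if (is.null(utr3)) utr3 <- emptyGL()
  new("GeneModels", genes = genes, exons = exons, utr5 = utr5, utr3 = utr3)
}

#' @rdname GeneModels-accessors
#' @export
setMethod("geneIds", "GeneModels", function(x) as.character(mcols(x@genes)$gene_id))

#' @rdname GeneModels-accessors
#' @export
setMethod("geneRanges", "GeneModels", function(x) x@genes)

#' @rdname GeneModels-accessors
#' @export
setMethod("tss", "GeneModels", function(x) {
  pos <- ifelse(as.character(strand(x@genes)) == "+",
                start(x@genes), end(x@genes))
  stats::setNames(as.integer(pos), geneIds(x))
})

#' @rdname GeneModels-accessors
#' @export
setMethod("tts", "GeneModels", function(x) {
  pos <- ifelse(as.character(strand(x@genes)) == "+",
                end(x@genes), start(x@genes))
  stats::setNames(as.integer(pos), geneIds(x))
})

#' @rdname GeneModels-accessors
#' @export
setMethod("exonRanges", "GeneModels", function(x) x@exons)

#' @rdname GeneModels-accessors
#' @export
setMethod("utr5Ranges", "GeneModels", function(x) x@utr5)

#' @rdname GeneModels-accessors
#' @export
setMethod("utr3Ranges", "GeneModels", function(x) x@utr3)

#' @rdname GeneModels-accessors
#' @export
setMethod("intronRanges", "GeneModels", function(x) {
  GenomicRanges::psetdiff(GenomicRanges::granges(x@genes), x@exons)
})

#' @describeIn GeneModels number of genes.
#' @param x a `GeneModels` object.
#' @export
setMethod("length", "GeneModels", function(x) length(x@genes))

#' @describeIn GeneModels subset by index, logical, or gene id.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "GeneModels", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, geneIds(x))
  new("GeneModels", genes = x@genes[i], exons = x@exons[i],
      utr5 = x@utr5[i], utr3 = x@utr3[i])
})

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels with %d gene(s) on %d sequence(s)\n",
              length(object),
              length(GenomeInfoDb::seqlevels(object@genes))))
  if (length(object))
    cat("  gene ids:", paste(utils::head(geneIds(object), 4), collapse = ", "),
        if (length(object) > 4) "..." else "", "\n")
})

#' @rdname SyntheticTruth-accessors
#' @export
setMethod("boundGenes", "SyntheticTruth", function(x) x@bound_genes)

#' @rdname SyntheticTruth-accessors
#' @export
setMethod("coexpressedGenes", "SyntheticTruth", function(x) x@coexpressed_genes)

#' @rdname SyntheticTruth-accessors
#' @export
setMethod("dtGenes", "SyntheticTruth", function(x) x@dt_genes)

#' @rdname SyntheticTruth-accessors
#' @export
setMethod("motifBearingSites", "SyntheticTruth", function(x) x@motif_bearing_sites)

#' @rdname SyntheticTruth-accessors
#' @export
setMethod("tfbOffsets", "SyntheticTruth", function(x) x@tf_b_offsets)

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(paste0("SyntheticTruth: %d bound, %d coexpressed, %d direct-",
                     "target gene(s); %d motif-bearing site(s)\n"),
              length(object@bound_genes), length(object@coexpressed_genes),
              length(object@dt_genes), length(object@motif_bearing_sites)))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: NRF = %.3f, fragment length estimate = %s bp\n",
              object@nrf,
              ifelse(length(object@fragment_length_estimate),
                     format(object@fragment_length_estimate), "NA")))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport\n")
  for (nm in names(object@counts))
    cat(sprintf("  %-22s %d\n", nm, object@counts[[nm]]))
})
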