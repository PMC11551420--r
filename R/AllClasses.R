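#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList start end width strand seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Gene models with sub-feature structure
#'
#' Container for a set of gene models: one genomic range per gene plus the
#' exon and UTR structure of its representative (longest) transcript.
#' Coordinates follow the Bioconductor convention (1-based, closed).  The
#' transcription start site (TSS) and termination site (TTS) are strand
#' aware: on the plus strand the TSS is the leftmost base, on the minus
#' strand the rightmost.
#'
#' @slot genes `GRanges` with one range per gene; `mcols()$gene_id` holds
#'   unique identifiers.
#' @slot exons `GRangesList` of exons per gene (genomic order), named by
#'   gene id.
#' @slot utr5,utr3 `GRangesList` of 5'/3' UTR segments per gene (possibly
#'   empty), named by gene id.
#'
#' @seealso [readGFF3()], [simulateGenomeAnnotation()]
#' @export
setClass("GeneModels",
  representation(genes = "GRanges", exons = "GRangesList",
                 utr5 = "GRangesList", utr3 = "GRangesList"))

setValidity("GeneModels", function(object) {
  g <- object@genes
  ids <- mcols(g)$gene_id
  if (length(g) == 0L) return(TRUE)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    return("every gene needs a non-empty gene_id")
  if (anyDuplicated(ids)) return("gene_id values must be unique")
  for (slotnm in c("exons", "utr5", "utr3")) {
    gl <- slot(object, slotnm)
    if (!identical(names(gl), as.character(ids)))
      return(sprintf("names of '%s' must match gene_id order", slotnm))
  }
  if (any(!as.character(strand(g)) %in% c("+", "-")))
    return("gene strand must be '+' or '-'")
  ex <- object@exons
  nex <- lengths(ex)
  if (any(nex == 0L)) return("each gene needs at least one exon")
  ue <- unlist(ex, use.names = FALSE)
  gi <- rep(seq_along(g), nex)
  if (any(start(ue) < start(g)[gi]) || any(end(ue) > end(g)[gi]))
    return("exons must be contained in the gene range")
  if (length(ue) > 1L) {
    same <- diff(gi) == 0L
    if (any(same & start(ue)[-1L] <= end(ue)[-length(ue)]))
      return("exons must be sorted and disjoint")
  }
  TRUE
})

#' Parameters of the synthetic study generator
#'
#' Bundles every knob of the synthetic data generator: genome composition,
#' gene placement, ChIP peak placement relative to the TSS, motif planting,
#' negative-binomial count structure with planted tissue effects, and the
#' second transcription factor's peak offsets.  Defaults encode the study
#' conditions the generator emulates; see the package vignette.
#'
#' @seealso [simulationConfig()] for construction with defaults.
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    n_chroms = "integer", chrom_length = "integer",
    n_genes = "integer", gene_length_range = "integer",
    gc_content = "numeric",
    n_peaks = "integer", peak_width = "integer",
    peak_offset_distribution = "list",
    motif = "ANY", motif_plant_rate = "numeric",
    site_width = "integer",
    replicate_jitter = "integer", replicate_noise = "numeric",
    n_samples_per_group = "integer",
    nb_mean_range = "numeric", nb_dispersion = "numeric",
    planted_fold_change = "numeric", fraction_coexpressed = "numeric",
    second_tf_offset_median = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@n_chroms < 1L || object@chrom_length < 1L)
    msg <- c(msg, "need at least one chromosome of positive length")
  if (object@n_genes < 0L) msg <- c(msg, "n_genes must be >= 0")
  if (object@gc_content < 0 || object@gc_content > 1)
    msg <- c(msg, "gc_content must be in [0, 1]")
  if (object@peak_width <= 0L) msg <- c(msg, "peak_width must be > 0")
  if (object@motif_plant_rate < 0 || object@motif_plant_rate > 1)
    msg <- c(msg, "motif_plant_rate must be in [0, 1]")
  if (object@replicate_noise < 0 || object@replicate_noise > 1)
    msg <- c(msg, "replicate_noise must be in [0, 1]")
  if (object@fraction_coexpressed < 0 || object@fraction_coexpressed > 1)
    msg <- c(msg, "fraction_coexpressed must be in [0, 1]")
  if (object@planted_fold_change < 1)
    msg <- c(msg, "planted_fold_change must be >= 1")
  if (object@nb_dispersion <= 0) msg <- c(msg, "nb_dispersion must be > 0")
  if (object@n_samples_per_group < 2L)
    msg <- c(msg, "n_samples_per_group must be >= 2")
  d <- object@peak_offset_distribution
  if (!all(c("weights", "means", "sds") %in% names(d)) ||
      length(d$weights) != length(d$means) ||
      length(d$means) != length(d$sds) ||
      abs(sum(d$weights) - 1) > 1e-8 || any(d$weights < 0))
    msg <- c(msg, "peak_offset_distribution needs weights/means/sds with weights summing to 1")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Planted ground truth of a synthetic study
#'
#' Records which genes were given a ChIP peak (`bound`), which were given a
#' planted tissue fold change (`coexpressed`), their intersection (`dt`,
#' the direct targets), which binding sites received a planted motif
#' instance, and the signed offsets at which the second factor's peaks were
#' placed.
#'
#' @export
setClass("SyntheticTruth",
  representation(bound_genes = "character", coexpressed_genes = "character",
                 dt_genes = "character", motif_bearing_sites = "character",
                 tf_b_offsets = "numeric"))

setValidity("SyntheticTruth", function(object) {
  if (!setequal(object@dt_genes,
                intersect(object@bound_genes, object@coexpressed_genes)))
    return("dt_genes must equal intersect(bound_genes, coexpressed_genes)")
  TRUE
})

#' Degenerate IUPAC consensus motif
#'
#' A named DNA motif written in the IUPAC degenerate alphabet, e.g. the
#' gapped AW Box `CNTNGNNNNNNNCG` or the CNC Box `CNCCNCC`.  Matching
#' semantics are double stranded by default: a region contains the motif if
#' either the pattern or its reverse complement matches.
#'
#' @slot name motif name.
#' @slot pattern consensus string over `ACGTRYSWKMBDHVN`.
#' @seealso [iupacMotif()], [scanMotif()], [motifPanel()]
#' @export
setClass("IUPACMotif", representation(name = "character", pattern = "character"))

setValidity("IUPACMotif", function(object) {
  if (length(object@pattern) != 1L || nchar(object@pattern) == 0L)
    return("pattern must be a single non-empty string")
  bad <- setdiff(strsplit(object@pattern, "")[[1]],
                 c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N"))
  if (length(bad))
    return(sprintf("invalid IUPAC code(s): %s", paste(bad, collapse = ", ")))
  if (length(object@name) != 1L || is.na(object@name) || object@name == "")
    return("motif needs a non-empty name")
  TRUE
})

#' ChIP library quality report
#'
#' Holds the nonredundant fraction (distinct tag positions over total
#' tags), the strand cross-correlation profile, and the fragment length
#' estimated as the cross-correlation argmax outside the read-length
#' phantom neighborhood.
#'
#' @export
setClass("QCReport",
  representation(nrf = "numeric", cc_profile = "data.frame",
                 fragment_length_estimate = "numeric", flags = "character"))

setValidity("QCReport", function(object) {
  if (length(object@nrf) && !is.na(object@nrf) &&
      (object@nrf <= 0 || object@nrf > 1))
    return("nrf must be in (0, 1]")
  if (nrow(object@cc_profile) &&
      any(abs(object@cc_profile$cc) > 1 + 1e-12, na.rm = TRUE))
    return("cross-correlation values must lie in [-1, 1]")
  TRUE
})

#' End-to-end pipeline report
#'
#' Machine-readable record of a [runFullPipeline()] run: stage counts, the
#' gene sets at each stage, result tables (enrichment, overlaps, profiles),
#' QC, and provenance (parameters and seed).
#'
#' @export
setClass("RunReport",
  representation(counts = "integer", sets = "list", tables = "list",
                 qc = "list", provenance = "list"))
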