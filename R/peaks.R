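#' @include genome-io.R
NULL

#' Nonredundant fraction of a ChIP tag library
#'
#' Distinct (chromosome, position, strand) tag triples divided by the total
#' tag count; the ENCODE library-complexity metric.
#'
#' @param tags `data.frame` with columns `chrom`, `pos`, `strand`.
#' @return A fraction in (0, 1].
#' @export
nonredundantFraction <- function(tags) {
  if (is.null(tags) || nrow(tags) == 0L)
    stop("no tags supplied", call. = FALSE)
  key <- paste(tags$chrom, tags$pos, tags$strand, sep = "\r")
  length(unique(key)) / nrow(tags)
}

#' Strand cross-correlation profile and fragment length estimate
#'
#' For each shift `s`, Pearson correlation of the plus-strand tag-start
#' coverage `plus[1..L-s]` with the minus-strand coverage `minus[s+1..L]`.
#' The fragment length is the argmax of the profile, excluding the phantom
#' neighborhood within `phantom_exclusion` bp of `read_length` when given.
#' A zero-variance vector at some shift yields correlation 0 with a
#' `"constant_coverage"` flag.
#'
#' @param plus_cov,minus_cov equal-length per-base tag-start count vectors.
#' @param shifts non-negative integer shifts to evaluate.
#' @param read_length read length whose phantom peak is masked (NULL = no
#'   masking).
#' @param phantom_exclusion half-width (bp) of the masked neighborhood.
#' @return A [QCReport-class] (with `nrf` unset, `NA`).
#' @export
strandCrossCorrelation <- function(plus_cov, minus_cov, shifts = 0:500,
                                   read_length = NULL,
                                   phantom_exclusion = 5L) {
  if (length(plus_cov) != length(minus_cov))
    stop("coverage vectors must have equal length", call. = FALSE)
  if (any(shifts < 0)) stop("shifts must be >= 0", call. = FALSE)
  L <- length(plus_cov)
  flags <- character()
  cc <- vapply(shifts, function(s) {
    x <- plus_cov[seq_len(L - s)]
    y <- minus_cov[seq.int(s + 1L, L)]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      flags <<- union(flags, "constant_coverage")
      return(0)
    }
    stats::cor(x, y)
  }, numeric(1))
  usable <- rep(TRUE, length(shifts))
  if (!is.null(read_length))
    usable <- abs(shifts - read_length) > phantom_exclusion
  est <- if (any(usable)) shifts[usable][which.max(cc[usable])] else NA_real_
  new("QCReport", nrf = NA_real_,
      cc_profile = data.frame(shift = shifts, cc = cc),
      fragment_length_estimate = as.numeric(est), flags = flags)
}

#' ChIP library QC from a tag table
#'
#' Convenience wrapper computing the nonredundant fraction and the strand
#' cross-correlation profile (summed over chromosomes' concatenated
#' coverage is avoided; the densest chromosome is used).
#'
#' @inheritParams nonredundantFraction
#' @param chrom_lengths named chromosome lengths.
#' @inheritParams strandCrossCorrelation
#' @return A [QCReport-class] with `nrf` filled in.
#' @export
chipQC <- function(tags, chrom_lengths, shifts = 0:500, read_length = NULL,
                   phantom_exclusion = 5L) {
  nrf <- nonredundantFraction(tags)
  top <- names(sort(table(tags$chrom), decreasing = TRUE))[1L]
  cov <- tagCoverage(tags, top, chrom_lengths[[top]])
  qc <- strandCrossCorrelation(cov$plus, cov$minus, shifts, read_length,
                               phantom_exclusion)
  qc@nrf <- nrf
  qc
}

#' Reproducible peaks across two replicates
#'
#' A replicate-A peak is reproducible when it overlaps at least one
#' replicate-B peak by >= 1 bp; coordinates and summit of the A peak are
#' kept, and each A peak is emitted at most once.
#'
#' @param rep_a,rep_b peak `GRanges`.
#' @return The reproducible subset of `rep_a`, coordinate sorted.
#' @export
reproduciblePeaks <- function(rep_a, rep_b) {
  hit <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(rep_a, rep_b, minoverlap = 1L,
                                ignore.strand = TRUE)))
  GenomicRanges::sort(rep_a[hit], ignore.strand = TRUE)
}

.signedTssDistance <- function(summit, tss_pos, plus) {
  ifelse(plus, summit - tss_pos, tss_pos - summit)
}

#' Assign peaks to genes through the bound window
#'
#' A gene is bound when some peak summit lies between `upstream_window` bp
#' upstream of its TSS and its TTS, in strand-aware coordinates.  A peak
#' may bind several genes; every such gene is reported.  Signed distances
#' run from the TSS to the summit (negative = upstream).
#'
#' @param peaks peak `GRanges` with a `summit` metadata column.
#' @param models a [GeneModels-class].
#' @param upstream_window upstream window width in bp (default 1000).
#' @return `list(bound_genes = character, links = data.frame(peak, gene_id,
#'   distance, zone))` with `zone` either `"upstream_window"` or
#'   `"gene_body"`.
#' @export
assignPeaksToGenes <- function(peaks, models, upstream_window = 1000L) {
  if (upstream_window < 0) stop("upstream_window must be >= 0", call. = FALSE)
  g <- geneRanges(models)
  plus <- as.character(strand(g)) == "+"
  win <- GRanges(seqnames(g),
                 IRanges(pmax(1L, start(g) - ifelse(plus, upstream_window, 0L)),
                         end(g) + ifelse(plus, 0L, upstream_window)))
  summit <- mcols(peaks)$summit
  sgr <- GRanges(seqnames(peaks), IRanges(summit, width = 1L))
  ov <- GenomicRanges::findOverlaps(sgr, win, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  tss_pos <- tss(models)
  links <- data.frame(
    peak = as.character(mcols(peaks)$name[qi]),
    gene_id = geneIds(models)[si],
    distance = as.integer(.signedTssDistance(summit[qi], tss_pos[si],
                                             plus[si])),
    stringsAsFactors = FALSE)
  links$zone <- ifelse(links$distance < 0L, "upstream_window", "gene_body")
  list(bound_genes = sort(unique(links$gene_id)), links = links)
}

.FEATURE_CATEGORIES <- c("utr5", "exon", "intron", "utr3", "upstream_2kb",
                         "downstream_1kb", "intergenic")

#' Genomic-feature annotation of peaks
#'
#' Classifies each peak by its summit into one of `utr5`, `exon`, `intron`,
#' `utr3`, `upstream_2kb` (2 kb upstream of the TSS), `downstream_1kb`
#' (1 kb downstream of the TTS) or `intergenic`, with gene-internal
#' categories taking precedence over flanking ones in the listed order.
#' Genes sharing a summit are resolved by precedence first, nearest TSS
#' second.  Fractions form a partition: they sum to 1.
#'
#' @inheritParams assignPeaksToGenes
#' @param upstream,downstream flanking zone widths in bp.
#' @return `list(assignment = character vector (category per peak), table =
#'   data.frame(category, count, fraction))`.
#' @export
annotatePeakFeatures <- function(peaks, models, upstream = 2000L,
                                 downstream = 1000L) {
  if (length(peaks) == 0L) stop("no peaks supplied", call. = FALSE)
  summit <- mcols(peaks)$summit
  sgr <- GRanges(seqnames(peaks), IRanges(summit, width = 1L))
  g <- geneRanges(models)
  plus <- as.character(strand(g)) == "+"
  tss_pos <- tss(models)

  catRanges <- list(
    utr5 = unlist(utr5Ranges(models)),
    exon = unlist(exonRanges(models)),
    intron = unlist(intronRanges(models)),
    utr3 = unlist(utr3Ranges(models)),
    upstream_2kb = GRanges(seqnames(g),
      IRanges(ifelse(plus, pmax(1L, start(g) - upstream), end(g) + 1L),
              ifelse(plus, pmax(0L, start(g) - 1L), end(g) + upstream))),
    downstream_1kb = GRanges(seqnames(g),
      IRanges(ifelse(plus, end(g) + 1L, pmax(1L, start(g) - downstream)),
              ifelse(plus, end(g) + downstream, pmax(0L, start(g) - 1L)))))

  geneOf <- list(
    utr5 = rep(seq_along(g), lengths(utr5Ranges(models))),
    exon = rep(seq_along(g), lengths(exonRanges(models))),
    intron = rep(seq_along(g), lengths(intronRanges(models))),
    utr3 = rep(seq_along(g), lengths(utr3Ranges(models))),
    upstream_2kb = seq_along(g), downstream_1kb = seq_along(g))

  n <- length(peaks)
  best_rank <- rep(7L, n)
  best_tssdist <- rep(Inf, n)
  for (r in seq_along(catRanges)) {
    rg <- catRanges[[r]]
    if (length(rg) == 0L) next
    ov <- GenomicRanges::findOverlaps(sgr, rg, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(ov)
    gi <- geneOf[[r]][S4Vectors::subjectHits(ov)]
    if (!length(qi)) next
    d <- abs(summit[qi] - tss_pos[gi])
    better <- r < best_rank[qi] | (r == best_rank[qi] & d < best_tssdist[qi])
    upd <- qi[better]
    best_rank[upd] <- r
    best_tssdist[upd] <- d[better]
  }
  assignment <- .FEATURE_CATEGORIES[best_rank]
  counts <- table(factor(assignment, levels = .FEATURE_CATEGORIES))
  list(assignment = assignment,
       table = data.frame(category = .FEATURE_CATEGORIES,
                          count = as.integer(counts),
                          fraction = as.numeric(counts) / n))
}

#' Histogram of signed peak-to-TSS distances
#'
#' @param links the `links` table from [assignPeaksToGenes()].
#' @param bin_width bin width in bp.
#' @return `data.frame(bin_start, bin_end, count)`; counts sum to
#'   `nrow(links)`.
#' @export
peakPositionProfile <- function(links, bin_width = 100L) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  d <- links$distance
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling((max(d) + 1) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- hist(d, breaks = breaks, right = FALSE, plot = FALSE)
  data.frame(bin_start = utils::head(breaks, -1L),
             bin_end = breaks[-1L], count = h$counts)
}

#' Summit-to-summit distances between two factors' peaks
#'
#' For every peak of factor A, the unsigned distance to the nearest
#' factor-B summit on the same chromosome.  A peaks with no same-chromosome
#' partner are excluded and counted.
#'
#' @param peaks_a,peaks_b peak `GRanges` with `summit` metadata columns.
#' @return `list(distances, median, min, max, n_excluded)`.
#' @export
peakDistanceBetweenTFs <- function(peaks_a, peaks_b) {
  if (length(peaks_a) == 0L || length(peaks_b) == 0L)
    stop("both peak sets must be non-empty", call. = FALSE)
  shared <- intersect(as.character(unique(seqnames(peaks_a))),
                      as.character(unique(seqnames(peaks_b))))
  if (length(shared) == 0L) {
    warning("no shared chromosome between the two peak sets")
    return(list(distances = numeric(), median = NA_real_, min = NA_real_,
                max = NA_real_, n_excluded = length(peaks_a)))
  }
  sa <- GRanges(seqnames(peaks_a), IRanges(mcols(peaks_a)$summit, width = 1L))
  sb <- GRanges(seqnames(peaks_b), IRanges(mcols(peaks_b)$summit, width = 1L))
  nb <- GenomicRanges::nearest(sa, sb, ignore.strand = TRUE)
  ok <- !is.na(nb)
  d <- abs(mcols(peaks_a)$summit[ok] - mcols(peaks_b)$summit[nb[ok]])
  list(distances = as.numeric(d), median = stats::median(d),
       min = min(d), max = max(d), n_excluded = sum(!ok))
}
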