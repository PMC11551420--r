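#' @include motifs.R set-stats.R peaks.R
NULL

#' Binding-site windows around peak summits
#'
#' The fixed-width window centered on each peak summit (default 100 bp; 50
#' bp for the two-factor comparison) together with its genomic sequence.
#'
#' @param peaks peak `GRanges` with `summit` metadata.
#' @param genome named `DNAStringSet`.
#' @param width window width in bp.
#' @return `list(regions = GRanges, seqs = DNAStringSet)` named by peak.
#' @export
bindingSites <- function(peaks, genome, width = 100L) {
  half <- width %/% 2L
  s <- mcols(peaks)$summit - half
  regions <- GRanges(seqnames(peaks), IRanges(s, width = width))
  names(regions) <- mcols(peaks)$name
  list(regions = regions, seqs = fetchSequence(genome, regions))
}

#' Matched random background regions
#'
#' For each binding site, a region of identical width placed at the site's
#' signed offset from the TSS of a uniformly drawn random gene (strand
#' aware), re-drawn when it falls outside the chromosome; this preserves
#' both the width multiset and the TSS-relative positional distribution of
#' the sites, the two covariates the site placement is biased in.
#'
#' @param offsets signed summit-to-TSS offsets of the sites (bp; negative =
#'   upstream).
#' @param width site width (bp).
#' @param models a [GeneModels-class].
#' @param genome named `DNAStringSet`.
#' @param n_per_site background regions per site.
#' @param seed RNG seed.
#' @param max_attempts placement attempts before failing.
#' @return `list(regions = GRanges, seqs = DNAStringSet)`.
#' @export
sampleMatchedBackground <- function(offsets, width, models, genome,
                                    n_per_site = 1L, seed = 1L,
                                    max_attempts = 1000L) {
  set.seed(.deriveSeed(seed, 55L))
  g <- geneRanges(models)
  plus <- as.character(strand(g)) == "+"
  tss_pos <- tss(models)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  half <- width %/% 2L
  offsets <- rep(as.integer(offsets), each = n_per_site)

  chrom <- character(length(offsets)); starts <- integer(length(offsets))
  for (i in seq_along(offsets)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      gi <- sample.int(length(g), 1L)
      center <- if (plus[gi]) tss_pos[gi] + offsets[i]
                else tss_pos[gi] - offsets[i]
      s <- center - half
      if (s >= 1L && s + width - 1L <= lens[as.character(seqnames(g))[gi]]) {
        chrom[i] <- as.character(seqnames(g))[gi]
        starts[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("could not place background region for site %d", i),
           call. = FALSE)
  }
  regions <- GRanges(chrom, IRanges(starts, width = width))
  names(regions) <- sprintf("bg_%05d", seq_along(regions))
  list(regions = regions, seqs = fetchSequence(genome, regions))
}

#' Motif enrichment in sites versus background regions
#'
#' Per motif: the fraction of binding sites versus background regions
#' containing at least one (double-strand) match, a one-sided Fisher exact
#' p-value (hypergeometric upper tail, enriched direction only) on the
#' 2x2 membership table, and Bonferroni adjustment over the motifs tested
#' in the call.
#'
#' @param site_seqs,background_seqs `DNAStringSet` or character vectors.
#' @param motifs list of [IUPACMotif-class] objects.
#' @param alpha significance threshold on the adjusted p-value.
#' @param both_strands scan both strands?
#' @return `data.frame(motif, n_sites, n_sites_with_motif, n_background,
#'   n_background_with_motif, observed_fraction, background_fraction,
#'   pvalue, adjusted_pvalue, significant)`.
#' @export
motifEnrichment <- function(site_seqs, background_seqs, motifs,
                            alpha = 0.01, both_strands = TRUE) {
  ns <- length(site_seqs); nb <- length(background_seqs)
  if (ns == 0L || nb == 0L)
    stop("both region sets must be non-empty", call. = FALSE)
  m <- length(motifs)
  res <- do.call(rbind, lapply(motifs, function(mo) {
    a <- sum(hasMotif(site_seqs, mo, both_strands))
    b <- sum(hasMotif(background_seqs, mo, both_strands))
    # P(overlap of the 'with motif' margin with sites >= a)
    p <- hypergeomUpperTail(a, ns + nb, a + b, ns)
    data.frame(motif = motifName(mo), n_sites = ns, n_sites_with_motif = a,
               n_background = nb, n_background_with_motif = b,
               observed_fraction = a / ns, background_fraction = b / nb,
               pvalue = p)
  }))
  res$adjusted_pvalue <- pmin(1, res$pvalue * m)
  res$significant <- res$adjusted_pvalue < alpha
  rownames(res) <- NULL
  res
}

#' TSS-relative region of each gene
#'
#' Strand-aware window upstream or downstream of the TSS, clipped to the
#' chromosome.
#'
#' @param models a [GeneModels-class].
#' @param genome named `DNAStringSet`.
#' @param direction `"downstream"` (TSS onward) or `"upstream"`.
#' @param width window width in bp (default 500).
#' @return `GRanges` named by gene id (gene strand retained).
#' @export
tssRegions <- function(models, genome, direction = c("downstream", "upstream"),
                       width = 500L) {
  direction <- match.arg(direction)
  g <- geneRanges(models)
  plus <- as.character(strand(g)) == "+"
  tss_pos <- tss(models)
  down <- direction == "downstream"
  # strand-aware offsets: downstream covers [0, width), upstream [-width, 0)
  s <- if (down) ifelse(plus, tss_pos, tss_pos - width + 1L)
       else ifelse(plus, tss_pos - width, tss_pos + 1L)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  maxlen <- lens[as.character(seqnames(g))]
  s <- pmax(1L, pmin(s, maxlen - width + 1L))
  regions <- GRanges(seqnames(g), IRanges(s, width = width),
                     strand = strand(g))
  names(regions) <- geneIds(models)
  regions
}

#' Empirical gene-set null for motif frequency
#'
#' Observed fraction of target genes whose TSS-relative region contains at
#' least one motif match, compared with the same fraction in `n_sets`
#' uniformly drawn random gene sets of matched size; the empirical p-value
#' is `(1 + #{background >= observed}) / (n_sets + 1)`.
#'
#' @param target_genes gene ids of the target set.
#' @param models a [GeneModels-class] supplying the gene universe.
#' @param genome named `DNAStringSet`.
#' @param motif an [IUPACMotif-class].
#' @param direction,width passed to [tssRegions()].
#' @param n_sets number of random sets (default 1000).
#' @param seed RNG seed.
#' @param both_strands scan both strands?
#' @return `list(observed_fraction, background_fractions, empirical_p)`.
#' @export
genesetMotifBackground <- function(target_genes, models, genome, motif,
                                   direction = "downstream", width = 500L,
                                   n_sets = 1000L, seed = 1L,
                                   both_strands = TRUE) {
  if (n_sets < 1L) stop("n_sets must be >= 1", call. = FALSE)
  ids <- geneIds(models)
  target_genes <- unique(target_genes)
  if (length(setdiff(target_genes, ids)))
    stop("target genes outside the annotation", call. = FALSE)
  if (length(target_genes) > length(ids))
    stop("target set larger than the gene universe", call. = FALSE)
  regions <- tssRegions(models, genome, direction, width)
  has <- hasMotif(fetchSequence(genome, regions), motif, both_strands)
  names(has) <- ids
  observed <- mean(has[target_genes])
  set.seed(.deriveSeed(seed, 66L))
  nk <- length(target_genes)
  bg <- vapply(seq_len(n_sets), function(i)
    mean(has[sample.int(length(ids), nk)]), numeric(1))
  list(observed_fraction = observed, background_fractions = bg,
       empirical_p = (1 + sum(bg >= observed)) / (n_sets + 1))
}

#' Positional distribution of motif matches around the TSS
#'
#' Scans the strand-aware window `[TSS - window, TSS + window)` of every
#' gene and bins the signed offsets of match starts (negative = upstream).
#' Genes whose window leaves the chromosome are skipped with a warning.
#'
#' @inheritParams genesetMotifBackground
#' @param window half-width of the scanned window (bp).
#' @param bin_width histogram bin width (bp).
#' @return `list(histogram = data.frame(bin_start, bin_end, count),
#'   n_matches, offsets)`.
#' @export
motifPositionalDistribution <- function(models, genome, motif,
                                        window = 1000L, bin_width = 100L,
                                        both_strands = TRUE) {
  if (window <= 0L) stop("window must be > 0", call. = FALSE)
  g <- geneRanges(models)
  plus <- as.character(strand(g)) == "+"
  tss_pos <- tss(models)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  # strand-aware window covering offsets [-window, window)
  s <- ifelse(plus, tss_pos - window, tss_pos - window + 1L)
  e <- ifelse(plus, tss_pos + window - 1L, tss_pos + window)
  ok <- s >= 1L & e <= lens[as.character(seqnames(g))]
  if (any(!ok))
    warning(sprintf("%d gene(s) skipped: TSS window out of bounds", sum(!ok)))
  regions <- GRanges(seqnames(g)[ok], IRanges(s[ok], e[ok]),
                     strand = strand(g)[ok])
  seqs <- fetchSequence(genome, regions)  # strand-aware: 5'->3' of the gene
  offsets <- unlist(lapply(seq_along(seqs), function(i) {
    scanMotif(seqs[[i]], motif, both_strands)$start - 1L - window
  }))
  if (is.null(offsets)) offsets <- integer()
  breaks <- seq(-ceiling(window / bin_width) * bin_width,
                ceiling(window / bin_width) * bin_width, by = bin_width)
  h <- hist(offsets, breaks = breaks, right = FALSE, plot = FALSE)
  list(histogram = data.frame(bin_start = utils::head(breaks, -1L),
                              bin_end = breaks[-1L], count = h$counts),
       n_matches = length(offsets), offsets = as.integer(offsets))
}
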