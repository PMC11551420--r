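#' @include motifs.R
NULL

#' Build a simulation configuration
#'
#' Returns a validated [SimulationConfig-class].  The defaults encode the
#' study conditions the generator emulates: peaks concentrated downstream
#' of the TSS (80/20 downstream/upstream Gaussian mixture truncated to the
#' bound window), a full AW Box planted in 56% of binding sites,
#' negative-binomial counts (dispersion 0.1) with a fourfold planted effect
#' in the two embryo-like groups for 20% of genes, replicate peaks jittered
#' by up to 10 bp with 10% replicate-unique noise, and second-factor peaks
#' at signed exponential offsets with median 142 bp.
#'
#' @param seed integer seed; every stage derives its own stream from it.
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes number of genes (placed without overlap, alternating
#'   strands).
#' @param gene_length_range min/max gene length (bp).
#' @param gc_content genome GC fraction.
#' @param n_peaks number of planted peaks (one per distinct gene).
#' @param peak_width called-peak width (bp).
#' @param peak_offset_distribution list with `weights`, `means`, `sds`:
#'   Gaussian mixture of signed summit offsets from the TSS (negative =
#'   upstream), truncated by rejection to the bound window.
#' @param motif [IUPACMotif-class] planted into binding sites.
#' @param motif_plant_rate fraction of binding sites receiving a planted
#'   concrete motif instance.
#' @param site_width binding-site window (bp) centered on the summit.
#' @param replicate_jitter maximum boundary jitter (bp) of replicate 2.
#' @param replicate_noise fraction of replicate-unique noise peaks added to
#'   each replicate.
#' @param n_samples_per_group RNA samples per tissue group.
#' @param nb_mean_range gene mean range (log-uniform draw).
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param planted_fold_change fold change applied in embryo-like groups to
#'   coexpressed genes (>= 1; 1 disables planting).
#' @param fraction_coexpressed fraction of genes receiving the effect.
#' @param second_tf_offset_median median of the signed exponential offsets
#'   (bp) of second-factor summits from first-factor summits.
#' @return A [SimulationConfig-class] object.
#' @export
simulationConfig <- function(seed = 1L,
                             n_chroms = 4L, chrom_length = 3200000L,
                             n_genes = 2000L,
                             gene_length_range = c(1000L, 3000L),
                             gc_content = 0.35,
                             n_peaks = 500L, peak_width = 200L,
                             peak_offset_distribution = list(
                               weights = c(0.8, 0.2),
                               means = c(500, -400),
                               sds = c(300, 250)),
                             motif = motifPanel()[["AW-Box"]],
                             motif_plant_rate = 0.56,
                             site_width = 100L,
                             replicate_jitter = 10L, replicate_noise = 0.1,
                             n_samples_per_group = 3L,
                             nb_mean_range = c(100, 1000),
                             nb_dispersion = 0.1,
                             planted_fold_change = 4,
                             fraction_coexpressed = 0.2,
                             second_tf_offset_median = 142) {
  new("SimulationConfig",
      seed = as.integer(seed), n_chroms = as.integer(n_chroms),
      chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
      gene_length_range = as.integer(gene_length_range),
      gc_content = gc_content, n_peaks = as.integer(n_peaks),
      peak_width = as.integer(peak_width),
      peak_offset_distribution = peak_offset_distribution,
      motif = motif, motif_plant_rate = motif_plant_rate,
      site_width = as.integer(site_width),
      replicate_jitter = as.integer(replicate_jitter),
      replicate_noise = replicate_noise,
      n_samples_per_group = as.integer(n_samples_per_group),
      nb_mean_range = as.numeric(nb_mean_range),
      nb_dispersion = nb_dispersion,
      planted_fold_change = planted_fold_change,
      fraction_coexpressed = fraction_coexpressed,
      second_tf_offset_median = second_tf_offset_median)
}

.randomChromosome <- function(len, gc) {
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  Biostrings::DNAString(paste(bases, collapse = ""))
}

# split a gene of length `len` into exons/introns/UTRs; returns local
# (1-based, relative to gene start) coordinates in genomic order
.geneStructure <- function(len, plus_strand) {
  n_ex <- if (len < 900L) 1L else sample(1:3, 1L)
  if (n_ex == 1L) {
    ex_start <- 1L; ex_end <- len
  } else {
    intron_len <- round(stats::runif(n_ex - 1L, 0.05, 0.15) * len)
    ex_tot <- len - sum(intron_len)
    u <- stats::runif(n_ex, 0.6, 1.4)
    ex_len <- floor(u / sum(u) * ex_tot)
    ex_len[n_ex] <- ex_tot - sum(ex_len[-n_ex])
    if (any(ex_len < 60L)) ex_len <- c(rep(ex_tot %/% n_ex, n_ex - 1L),
                                       ex_tot - (n_ex - 1L) * (ex_tot %/% n_ex))
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    pos <- 1L
    for (k in seq_len(n_ex)) {
      ex_start[k] <- pos
      ex_end[k] <- pos + ex_len[k] - 1L
      pos <- ex_end[k] + (if (k < n_ex) intron_len[k] else 0L) + 1L
    }
    ex_end[n_ex] <- len
  }
  first_len <- ex_end[1L] - ex_start[1L] + 1L
  last_len <- ex_end[n_ex] - ex_start[n_ex] + 1L
  u5 <- min(round(stats::runif(1, 100, 300)), first_len - 30L)
  u3 <- min(round(stats::runif(1, 100, 300)), last_len - 30L)
  # 5' end is the left end on +, the right end on -
  if (plus_strand) {
    utr5 <- if (u5 > 0) c(ex_start[1L], ex_start[1L] + u5 - 1L)
    utr3 <- if (u3 > 0) c(ex_end[n_ex] - u3 + 1L, ex_end[n_ex])
  } else {
    utr5 <- if (u5 > 0) c(ex_end[n_ex] - u5 + 1L, ex_end[n_ex])
    utr3 <- if (u3 > 0) c(ex_start[1L], ex_start[1L] + u3 - 1L)
  }
  list(ex_start = ex_start, ex_end = ex_end, utr5 = utr5, utr3 = utr3)
}

#' Simulate a genome and gene annotation
#'
#' Generates i.i.d. chromosome sequences at the configured GC fraction and
#' places non-overlapping genes with alternating strands, at least 2.1 kb
#' apart so that each gene's upstream window and flanking zones are
#' unambiguous.  Deterministic under the config seed.
#'
#' @param config a [SimulationConfig-class].
#' @return `list(genome = DNAStringSet, models = GeneModels)`.
#' @export
simulateGenomeAnnotation <- function(config) {
  set.seed(.deriveSeed(config@seed, 11L))
  genome <- Biostrings::DNAStringSet(lapply(seq_len(config@n_chroms),
    function(i) .randomChromosome(config@chrom_length, config@gc_content)))
  names(genome) <- paste0("chr", seq_len(config@n_chroms))
  if (config@n_genes == 0L)
    return(list(genome = genome,
                models = GeneModels(GRanges(gene_id = character()))))

  chrom <- integer(config@n_genes); gstart <- integer(config@n_genes)
  glen <- integer(config@n_genes)
  cur_chrom <- 1L
  cursor <- 2500L
  for (i in seq_len(config@n_genes)) {
    len <- sample(config@gene_length_range[1L]:config@gene_length_range[2L], 1L)
    gap <- round(stats::runif(1, 2100, 3000))
    if (cursor + gap + len + 1200L > config@chrom_length) {
      cur_chrom <- cur_chrom + 1L
      cursor <- 2500L
      if (cur_chrom > config@n_chroms)
        stop("genes cannot be placed without overlap: enlarge the genome",
             call. = FALSE)
    }
    gstart[i] <- cursor + gap
    glen[i] <- len
    chrom[i] <- cur_chrom
    cursor <- gstart[i] + len
  }
  strands <- rep(c("+", "-"), length.out = config@n_genes)
  ids <- sprintf("gene%04d", seq_len(config@n_genes))

  # accumulate feature coordinates, then build each GRangesList in one shot
  acc <- list(ex = list(), u5 = list(), u3 = list())
  for (i in seq_len(config@n_genes)) {
    st <- .geneStructure(glen[i], strands[i] == "+")
    acc$ex[[i]] <- cbind(i, gstart[i] + st$ex_start - 1L,
                         gstart[i] + st$ex_end - 1L)
    acc$u5[[i]] <- if (is.null(st$utr5)) NULL else
      cbind(i, gstart[i] + st$utr5[1L] - 1L, gstart[i] + st$utr5[2L] - 1L)
    acc$u3[[i]] <- if (is.null(st$utr3)) NULL else
      cbind(i, gstart[i] + st$utr3[1L] - 1L, gstart[i] + st$utr3[2L] - 1L)
  }
  lev <- factor(seq_len(config@n_genes))
  mkGL <- function(rows) {
    m <- do.call(rbind, rows)
    if (is.null(m)) m <- matrix(integer(), ncol = 3L)
    gr <- GRanges(paste0("chr", chrom[m[, 1L]]),
                  IRanges(m[, 2L], m[, 3L]), strand = strands[m[, 1L]])
    gl <- GenomicRanges::split(gr, factor(m[, 1L], levels = lev))
    names(gl) <- ids
    gl
  }
  g <- GRanges(paste0("chr", chrom),
               IRanges(gstart, gstart + glen - 1L), strand = strands)
  mcols(g)$gene_id <- ids
  list(genome = genome,
       models = GeneModels(g, exons = mkGL(acc$ex), utr5 = mkGL(acc$u5),
                           utr3 = mkGL(acc$u3)))
}

.drawOffsets <- function(n, dist) {
  comp <- sample.int(length(dist$weights), n, replace = TRUE,
                     prob = dist$weights)
  round(stats::rnorm(n, dist$means[comp], dist$sds[comp]))
}

.mkPeakGR <- function(chrom, summit, width, names, lens) {
  half <- width %/% 2L
  s <- pmax(1L, summit - half)
  e <- pmin(lens[chrom], s + width - 1L)
  gr <- GRanges(chrom, IRanges(s, e))
  mcols(gr)$name <- names
  mcols(gr)$score <- 0
  mcols(gr)$summit <- as.integer(summit)
  gr
}

#' Simulate replicate ChIP peak sets with planted motifs and a second factor
#'
#' For `n_peaks` distinct genes a summit is drawn from the TSS-offset
#' mixture (rejected until it falls in the bound window, 1 kb upstream of
#' the TSS through the gene body).  A fraction `motif_plant_rate` of
#' binding sites receives a concrete motif instance (degenerate positions
#' resolved uniformly) written into the genome under the summit window.
#' Replicate 2 carries the same peaks with boundaries jittered by at most
#' `replicate_jitter` bp; both replicates additionally receive a fraction
#' `replicate_noise` of replicate-unique noise peaks placed uniformly.
#' Second-factor summits sit at signed exponential offsets (median
#' `second_tf_offset_median`) from first-factor summits.
#'
#' @param genome `DNAStringSet` from [simulateGenomeAnnotation()].
#' @param models matching [GeneModels-class].
#' @param config the [SimulationConfig-class] used throughout.
#' @return List with elements `genome` (with planted motifs), `rep_a`,
#'   `rep_b`, `tf_b` (peak `GRanges`), `bound_genes`,
#'   `motif_bearing_sites`, `tf_b_offsets`.
#' @export
simulatePeaksAndMotifs <- function(genome, models, config) {
  if (motifLength(config@motif) > config@site_width)
    stop("motif longer than the binding-site window", call. = FALSE)
  if (config@n_peaks > length(models))
    stop("n_peaks exceeds the number of genes", call. = FALSE)
  set.seed(.deriveSeed(config@seed, 22L))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))

  idx <- sort(sample.int(length(models), config@n_peaks))
  bound <- geneIds(models)[idx]
  g <- geneRanges(models)[idx]
  tss_pos <- tss(models)[idx]
  plus <- as.character(strand(g)) == "+"
  glen <- width(g)

  summit <- integer(config@n_peaks)
  for (i in seq_len(config@n_peaks)) {
    for (attempt in seq_len(1000L)) {
      off <- .drawOffsets(1L, config@peak_offset_distribution)
      if (off >= -1000L && off <= glen[i] - 1L) break
      if (attempt == 1000L) stop("could not draw a valid peak offset")
    }
    summit[i] <- if (plus[i]) tss_pos[i] + off else tss_pos[i] - off
  }
  chrom <- as.character(seqnames(g))
  rep_a <- .mkPeakGR(chrom, summit, config@peak_width,
                     sprintf("peakA_%04d", seq_len(config@n_peaks)), lens)

  # plant concrete motif instances into the binding-site windows
  planted <- which(stats::runif(config@n_peaks) < config@motif_plant_rate)
  m <- motifLength(config@motif)
  half <- config@site_width %/% 2L
  if (length(planted)) {
    ins_start <- vapply(planted, function(i) {
      lo <- summit[i] - half
      hi <- summit[i] + (config@site_width - half - 1L) - m + 1L
      as.integer(lo + sample.int(hi - lo + 1L, 1L) - 1L)
    }, integer(1))
    inst <- vapply(planted, function(i) resolveIUPAC(config@motif),
                   character(1))
    for (ch in unique(chrom[planted])) {
      sel <- planted[chrom[planted] == ch]
      selpos <- ins_start[match(sel, planted)]
      genome[[ch]] <- Biostrings::replaceAt(
        genome[[ch]], IRanges(selpos, selpos + m - 1L),
        Biostrings::DNAStringSet(inst[match(sel, planted)]))
    }
  }
  motif_sites <- mcols(rep_a)$name[planted]

  # replicate 2: jittered boundaries, summit preserved
  j <- config@replicate_jitter
  s2 <- pmax(1L, pmin(start(rep_a) + sample(seq(-j, j), config@n_peaks,
                                            replace = TRUE), summit))
  e2 <- pmin(lens[chrom], pmax(end(rep_a) + sample(seq(-j, j),
                                                   config@n_peaks,
                                                   replace = TRUE), summit))
  rep_b <- GRanges(chrom, IRanges(s2, e2))
  mcols(rep_b)$name <- sprintf("peakB_%04d", seq_len(config@n_peaks))
  mcols(rep_b)$score <- 0
  mcols(rep_b)$summit <- summit

  addNoise <- function(gr, tag) {
    n_noise <- round(config@replicate_noise * config@n_peaks)
    if (n_noise == 0L) return(gr)
    nch <- sample(names(genome), n_noise, replace = TRUE)
    npos <- vapply(nch, function(ch)
      sample.int(lens[ch] - config@peak_width, 1L) + config@peak_width %/% 2L,
      integer(1))
    suppressWarnings(c(gr, .mkPeakGR(nch, npos, config@peak_width,
                                     sprintf("noise%s_%04d", tag,
                                             seq_len(n_noise)), lens)))
  }
  rep_a <- GenomicRanges::sort(addNoise(rep_a, "A"), ignore.strand = TRUE)
  rep_b <- GenomicRanges::sort(addNoise(rep_b, "B"), ignore.strand = TRUE)

  # second factor: signed exponential offsets from first-factor summits
  rate <- log(2) / config@second_tf_offset_median
  off_b <- integer(config@n_peaks)
  for (i in seq_len(config@n_peaks)) {
    for (attempt in seq_len(1000L)) {
      d <- as.integer(round(stats::rexp(1L, rate))) *
        sample(c(-1L, 1L), 1L)
      sb <- summit[i] + d
      if (sb > half && sb + half <= lens[chrom[i]]) break
      if (attempt == 1000L) stop("could not place a second-factor peak")
    }
    off_b[i] <- d
  }
  tf_b <- .mkPeakGR(chrom, summit + off_b, config@peak_width,
                    sprintf("peakTFB_%04d", seq_len(config@n_peaks)), lens)
  tf_b <- GenomicRanges::sort(tf_b, ignore.strand = TRUE)

  list(genome = genome, rep_a = rep_a, rep_b = rep_b, tf_b = tf_b,
       bound_genes = bound, motif_bearing_sites = motif_sites,
       tf_b_offsets = off_b)
}

#' Tissue groups used by the simulated expression study
#'
#' Two embryo-like groups and two seed-coat-like groups; coexpression is
#' defined by up-regulation in embryo versus seed-coat contrasts.
#'
#' @return Character vector of the four group names.
#' @export
tissueGroups <- function() {
  c("embryo_abaxial", "embryo_adaxial", "seedcoat_hilum", "seedcoat_parenchyma")
}

#' Simulate a count matrix with planted tissue effects
#'
#' Negative-binomial counts for four tissue groups; a fraction
#' `fraction_coexpressed` of genes has its mean multiplied by
#' `planted_fold_change` in the two embryo-like groups.  With fold change 1
#' nothing is planted and the coexpressed truth set is empty.
#'
#' @param models [GeneModels-class] supplying gene ids.
#' @param config a [SimulationConfig-class].
#' @return `list(se = SummarizedExperiment (assay "counts", colData$group),
#'   coexpressed_genes = character)`.
#' @export
simulateCounts <- function(models, config) {
  set.seed(.deriveSeed(config@seed, 33L))
  ids <- geneIds(models)
  n <- length(ids)
  groups <- tissueGroups()
  reps <- config@n_samples_per_group
  group <- rep(groups, each = reps)
  samples <- paste0(group, "_r", rep(seq_len(reps), times = length(groups)))

  mu0 <- exp(stats::runif(n, log(config@nb_mean_range[1L]),
                          log(config@nb_mean_range[2L])))
  coex <- if (config@planted_fold_change > 1) {
    sort(sample(ids, round(config@fraction_coexpressed * n)))
  } else character()
  fc <- ifelse(ids %in% coex, config@planted_fold_change, 1)

  size <- 1 / config@nb_dispersion
  counts <- matrix(0L, nrow = n, ncol = length(samples),
                   dimnames = list(ids, samples))
  embryo <- group %in% groups[1:2]
  for (jcol in seq_along(samples)) {
    mu <- if (embryo[jcol]) mu0 * fc else mu0
    counts[, jcol] <- stats::rnbinom(n, size = size, mu = mu)
  }
  se <- makeCountMatrix(counts, group)
  list(se = se, coexpressed_genes = coex)
}

#' Assemble a count matrix container
#'
#' Validates non-negative integer counts and a complete sample-to-group
#' mapping and wraps them in a `SummarizedExperiment`.
#'
#' @param counts gene x sample matrix of non-negative integers with
#'   dimnames.
#' @param group character vector of group labels, one per sample.
#' @return `SummarizedExperiment` with assay `counts`.
#' @export
makeCountMatrix <- function(counts, group) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (length(group) != ncol(counts) || anyNA(group) || any(group == ""))
    stop("every sample needs a group label", call. = FALSE)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(group = group,
                                   row.names = colnames(counts)))
}

#' Simulate ChIP tag positions around peak summits
#'
#' Emits plus-strand tags at fragment starts and minus-strand tags at
#' fragment ends for fragments of fixed length centered near each summit;
#' used to exercise the library QC metrics (NRF, strand cross-correlation).
#'
#' @param peaks peak `GRanges` with a `summit` metadata column.
#' @param chrom_lengths named chromosome lengths.
#' @param fragment_length fragment length in bp.
#' @param tags_per_peak fragments sampled per peak.
#' @param center_sd Gaussian spread of fragment centers around the summit.
#' @param seed RNG seed.
#' @return `data.frame` with columns `chrom`, `pos`, `strand`.
#' @export
simulateChipTags <- function(peaks, chrom_lengths, fragment_length = 250L,
                             tags_per_peak = 20L, center_sd = 20, seed = 1L) {
  set.seed(.deriveSeed(seed, 44L))
  n <- length(peaks) * tags_per_peak
  chrom <- rep(as.character(seqnames(peaks)), each = tags_per_peak)
  summit <- rep(mcols(peaks)$summit, each = tags_per_peak)
  center <- summit + round(stats::rnorm(n, 0, center_sd))
  s <- center - fragment_length %/% 2L
  e <- s + fragment_length - 1L
  lens <- chrom_lengths[chrom]
  keep <- s >= 1L & e <= lens
  data.frame(chrom = c(chrom[keep], chrom[keep]),
             pos = as.integer(c(s[keep], e[keep])),
             strand = rep(c("+", "-"), each = sum(keep)))
}

#' Per-base tag-start coverage for one chromosome
#'
#' @param tags `data.frame(chrom, pos, strand)`.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length.
#' @return `list(plus, minus)` integer vectors of length `chrom_length`.
#' @export
tagCoverage <- function(tags, chrom, chrom_length) {
  sel <- tags$chrom == chrom
  list(plus = tabulate(tags$pos[sel & tags$strand == "+"], chrom_length),
       minus = tabulate(tags$pos[sel & tags$strand == "-"], chrom_length))
}

#' Simulate a complete study with planted ground truth
#'
#' Runs genome/annotation, peak/motif and count simulation under one seed
#' and assembles the planted truth.  When `dir` is given, writes the full
#' file set (`genome.fa`, `annotation.gff3`, `tf_a_rep1.narrowPeak`,
#' `tf_a_rep2.narrowPeak`, `tf_b.narrowPeak`, `counts.tsv`, `groups.tsv`,
#' `truth.json`) with deterministic bytes.
#'
#' @param config a [SimulationConfig-class].
#' @param dir optional output directory (created if needed).
#' @return List with `genome`, `models`, `rep_a`, `rep_b`, `tf_b`, `se`,
#'   `truth` ([SyntheticTruth-class]) and, if written, `paths`.
#' @export
simulateDataset <- function(config, dir = NULL) {
  ga <- simulateGenomeAnnotation(config)
  pk <- simulatePeaksAndMotifs(ga$genome, ga$models, config)
  cx <- simulateCounts(ga$models, config)
  truth <- new("SyntheticTruth",
               bound_genes = pk$bound_genes,
               coexpressed_genes = cx$coexpressed_genes,
               dt_genes = sort(intersect(pk$bound_genes, cx$coexpressed_genes)),
               motif_bearing_sites = pk$motif_bearing_sites,
               tf_b_offsets = as.numeric(pk$tf_b_offsets))
  out <- list(genome = pk$genome, models = ga$models, rep_a = pk$rep_a,
              rep_b = pk$rep_b, tf_b = pk$tf_b, se = cx$se, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- list(genome = file.path(dir, "genome.fa"),
              annotation = file.path(dir, "annotation.gff3"),
              rep_a = file.path(dir, "tf_a_rep1.narrowPeak"),
              rep_b = file.path(dir, "tf_a_rep2.narrowPeak"),
              tf_b = file.path(dir, "tf_b.narrowPeak"),
              counts = file.path(dir, "counts.tsv"),
              groups = file.path(dir, "groups.tsv"),
              truth = file.path(dir, "truth.json"))
    Biostrings::writeXStringSet(out$genome, p$genome, width = 80L)
    writeGFF3(out$models, p$annotation)
    writeNarrowPeak(out$rep_a, p$rep_a)
    writeNarrowPeak(out$rep_b, p$rep_b)
    writeNarrowPeak(out$tf_b, p$tf_b)
    writeCountsTSV(out$se, p$counts, p$groups)
    writeTruthJSON(truth, p$truth)
    out$paths <- p
  }
  out
}

#' Read/write count matrices as TSV
#'
#' `writeCountsTSV()` writes the counts (genes x samples, rownames in the
#' first column) and a two-column sample/group table; `readCountsTSV()`
#' reads them back into a `SummarizedExperiment`.
#'
#' @param se `SummarizedExperiment` with assay `counts` and `colData$group`.
#' @param counts_path,groups_path file paths.
#' @return `readCountsTSV()`: the `SummarizedExperiment`.
#' @export
writeCountsTSV <- function(se, counts_path, groups_path) {
  m <- SummarizedExperiment::assay(se, "counts")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(se),
               group = SummarizedExperiment::colData(se)$group),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' @rdname writeCountsTSV
#' @export
readCountsTSV <- function(counts_path, groups_path) {
  df <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  gr <- utils::read.table(groups_path, sep = "\t", header = TRUE)
  makeCountMatrix(m, gr$group[match(colnames(m), gr$sample)])
}

#' Read/write planted truth as JSON
#'
#' @param truth a [SyntheticTruth-class].
#' @param path JSON path.
#' @return `readTruthJSON()`: the [SyntheticTruth-class].
#' @export
writeTruthJSON <- function(truth, path) {
  jsonlite::write_json(
    list(bound_genes = boundGenes(truth),
         coexpressed_genes = coexpressedGenes(truth),
         dt_genes = dtGenes(truth),
         motif_bearing_sites = motifBearingSites(truth),
         tf_b_offsets = tfbOffsets(truth)),
    path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruthJSON
#' @export
readTruthJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  asc <- function(v) if (length(v)) as.character(v) else character()
  new("SyntheticTruth", bound_genes = asc(x$bound_genes),
      coexpressed_genes = asc(x$coexpressed_genes),
      dt_genes = asc(x$dt_genes),
      motif_bearing_sites = asc(x$motif_bearing_sites),
      tf_b_offsets = as.numeric(x$tf_b_offsets))
}
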