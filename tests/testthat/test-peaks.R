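test_that("nonredundant fraction counts distinct tag positions", {
  tags <- data.frame(chrom = "chr1", pos = 1:10, strand = "+")
  expect_equal(nonredundantFraction(tags), 1.0)
  dup <- data.frame(chrom = "chr1", pos = rep(1:5, 2), strand = "+")
  expect_equal(nonredundantFraction(dup), 0.5)
  expect_error(nonredundantFraction(tags[0, ]), "no tags")

  # brute-force distinct count on a random multiset
  set.seed(3)
  rnd <- data.frame(chrom = sample(c("chr1", "chr2"), 500, TRUE),
                    pos = sample(100L, 500, TRUE),
                    strand = sample(c("+", "-"), 500, TRUE))
  expect_equal(nonredundantFraction(rnd),
               nrow(unique(rnd)) / nrow(rnd))
})

test_that("strand cross-correlation finds the planted shift", {
  set.seed(4)
  L <- 10000L
  plus <- rpois(L, 0.05)
  minus <- c(rep(0L, 120L), plus[1:(L - 120L)])  # exact 120 bp shift
  qc <- strandCrossCorrelation(plus, minus, shifts = 0:300)
  expect_equal(qc@fragment_length_estimate, 120)

  # independent vectors: no strong correlation anywhere
  qc0 <- strandCrossCorrelation(rpois(L, 0.05), rpois(L, 0.05),
                                shifts = 0:300)
  expect_lt(max(abs(qc0@cc_profile$cc)), 0.2)

  # constant coverage: flagged, correlation 0
  qcc <- strandCrossCorrelation(rep(1L, 100), rpois(100, 1), shifts = 0:5)
  expect_true("constant_coverage" %in% qcc@flags)
  expect_true(all(qcc@cc_profile$cc == 0))

  # planted fragment length recovered from simulated tags
  d <- smallSim()
  lens <- chromLengths(d$genome)
  tags <- simulateChipTags(d$rep_a, lens, fragment_length = 250L,
                           tags_per_peak = 40L, seed = 6L)
  qcf <- chipQC(tags, lens, shifts = seq(100L, 400L, 2L), read_length = 50L)
  expect_lte(abs(qcf@fragment_length_estimate - 250), 5)
  expect_gt(qcf@nrf, 0); expect_lte(qcf@nrf, 1)
})

test_that("reproducible peaks obey identity, disjointness and recovery", {
  d <- smallSim()
  expect_identical(reproduciblePeaks(d$rep_a, d$rep_a),
                   GenomicRanges::sort(d$rep_a, ignore.strand = TRUE))
  far <- GenomicRanges::shift(d$rep_a, 100000L)
  expect_lte(length(reproduciblePeaks(d$rep_a, far)), length(d$rep_a))
  disj <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 10))
  disj$name <- "z"; disj$summit <- 5L
  expect_length(suppressWarnings(reproduciblePeaks(disj, d$rep_a)), 0L)

  # jittered replicates with 10% noise: planted peaks always recovered
  rp <- reproduciblePeaks(d$rep_a, d$rep_b)
  planted_names <- sprintf("peakA_%04d", seq_along(boundGenes(d$truth)))
  expect_true(all(planted_names %in% rp$name))
})

test_that("peak-to-gene assignment follows the strand-aware bound window", {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 8000),
                              strand = "+")
  S4Vectors::mcols(g)$gene_id <- "gPlus"
  m <- GeneModels(g)
  mkpk <- function(summits) {
    pk <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(summits - 50L, summits + 50L))
    pk$name <- sprintf("p%d", seq_along(summits)); pk$summit <- summits
    pk
  }
  res <- assignPeaksToGenes(mkpk(c(4002L, 4000L, 7500L, 4001L)), m)
  expect_setequal(res$bound_genes, "gPlus")
  expect_setequal(res$links$peak, c("p1", "p3", "p4"))
  expect_equal(res$links$distance[res$links$peak == "p1"], -999L)
  expect_equal(res$links$distance[res$links$peak == "p4"], -1000L)
  expect_equal(res$links$zone[res$links$peak == "p3"], "gene_body")
  expect_equal(res$links$zone[res$links$peak == "p1"], "upstream_window")

  # minus-strand mirror: TSS at the right end, upstream to the right
  gm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 8000),
                               strand = "-")
  S4Vectors::mcols(gm)$gene_id <- "gMinus"
  mm <- GeneModels(gm)
  resm <- assignPeaksToGenes(mkpk(c(8500L, 9200L, 6000L)), mm)
  lk <- resm$links
  expect_setequal(lk$peak, c("p1", "p3"))
  expect_equal(lk$distance[lk$peak == "p1"], -500L)
  expect_equal(lk$zone[lk$peak == "p1"], "upstream_window")
  expect_equal(lk$zone[lk$peak == "p3"], "gene_body")
  expect_error(assignPeaksToGenes(mkpk(100L), m, upstream_window = -1),
               "upstream_window")
})

test_that("assignment is invariant under genome-wide translation", {
  d <- smallSim()
  base <- assignPeaksToGenes(d$rep_a, d$models)
  shift_models <- GeneModels(
    GenomicRanges::shift(geneRanges(d$models), 1234L),
    exons = GenomicRanges::shift(exonRanges(d$models), 1234L),
    utr5 = GenomicRanges::shift(utr5Ranges(d$models), 1234L),
    utr3 = GenomicRanges::shift(utr3Ranges(d$models), 1234L))
  pk <- GenomicRanges::shift(d$rep_a, 1234L)
  pk$summit <- pk$summit + 1234L
  moved <- assignPeaksToGenes(pk, shift_models)
  expect_identical(base$bound_genes, moved$bound_genes)
  ordb <- order(base$links$peak, base$links$gene_id)
  ordm <- order(moved$links$peak, moved$links$gene_id)
  expect_identical(base$links$distance[ordb], moved$links$distance[ordm])
})

test_that("feature annotation applies precedence and forms a partition", {
  # gene A (+): 5' UTR 101-150; gene B starts at 1100, so 2 kb upstream of
  # B covers A's UTR; the summit at 120 must still be utr5
  f <- writeToyGFF3(tempfile(), lines = c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t101\t700\t.\t+\t.\tID=gA",
    "chr1\ttoy\tmRNA\t101\t700\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\ttoy\texon\t101\t300\t.\t+\t.\tID=gA.1.e1;Parent=gA.1",
    "chr1\ttoy\texon\t401\t700\t.\t+\t.\tID=gA.1.e2;Parent=gA.1",
    "chr1\ttoy\tfive_prime_UTR\t101\t150\t.\t+\t.\tID=gA.1.u5;Parent=gA.1",
    "chr1\ttoy\tgene\t1100\t1600\t.\t+\t.\tID=gB",
    "chr1\ttoy\tmRNA\t1100\t1600\t.\t+\t.\tID=gB.1;Parent=gB",
    "chr1\ttoy\texon\t1100\t1600\t.\t+\t.\tID=gB.1.e1;Parent=gB.1"))
  m <- readGFF3(f)
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(120, 350, 200, 900),
                                                        width = 1L))
  pk$name <- paste0("p", 1:4)
  pk$summit <- c(120L, 350L, 200L, 900L)
  ann <- annotatePeakFeatures(pk, m)
  expect_identical(ann$assignment,
                   c("utr5", "intron", "exon", "upstream_2kb"))
  expect_equal(sum(ann$table$fraction), 1)

  # no genes at all: everything intergenic
  empty <- GeneModels(GenomicRanges::GRanges(gene_id = character()))
  ann0 <- annotatePeakFeatures(pk, empty)
  expect_true(all(ann0$assignment == "intergenic"))

  # fuzz: fractions always sum to 1 and every peak is counted once
  d <- smallSim()
  lens <- chromLengths(d$genome)
  set.seed(31)
  for (i in 1:8) {
    n <- sample(20:80, 1)
    ch <- sample(names(lens), n, replace = TRUE)
    pos <- vapply(ch, function(c0) sample.int(lens[[c0]], 1L), integer(1))
    fz <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos, width = 1L))
    fz$name <- paste0("f", seq_len(n)); fz$summit <- as.integer(pos)
    tab <- annotatePeakFeatures(fz, d$models)$table
    expect_equal(sum(tab$fraction), 1, tolerance = 1e-9)
    expect_equal(sum(tab$count), n)
  }
})

test_that("peak position profile conserves counts and bins correctly", {
  links <- data.frame(peak = "p", gene_id = "g", distance = c(0L, 10L, 99L),
                      zone = "gene_body")
  h <- peakPositionProfile(links, bin_width = 100L)
  expect_equal(sum(h$count), 3L)
  expect_equal(h$count[h$bin_start == 0], 3L)
  expect_error(peakPositionProfile(links, bin_width = 0), "bin_width")

  d <- smallSim()
  lk <- assignPeaksToGenes(d$rep_a, d$models)$links
  h2 <- peakPositionProfile(lk, 50L)
  expect_equal(sum(h2$count), nrow(lk))
  # offsets drawn downstream-heavy: the mode is downstream of the TSS
  expect_gt(sum(h2$count[h2$bin_start >= 0]), sum(h2$count[h2$bin_start < 0]))
})

test_that("two-factor summit distances are nearest-neighbor and unsigned", {
  mk <- function(ch, summits, nm) {
    gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(summits - 10L,
                                                      summits + 10L))
    gr$name <- paste0(nm, seq_along(summits)); gr$summit <- summits
    gr
  }
  a <- mk("chr1", 100L, "a"); b <- mk("chr1", 242L, "b")
  res <- peakDistanceBetweenTFs(a, b)
  expect_equal(res$distances, 142)
  expect_equal(res$median, 142)
  same <- peakDistanceBetweenTFs(a, a)
  expect_equal(same$distances, 0)

  # peaks with no same-chromosome partner are excluded and counted
  a2 <- suppressWarnings(c(mk("chr1", c(100L, 500L), "a"),
                           mk("chrOnlyA", 300L, "x")))
  res2 <- peakDistanceBetweenTFs(a2, b)
  expect_equal(res2$n_excluded, 1L)
  expect_length(res2$distances, 2L)
  expect_warning(peakDistanceBetweenTFs(mk("chrQ", 5L, "q"), b), "shared")

  # synthetic second factor: measured median close to the planted offsets
  d <- midSim()
  pa <- d$rep_a[grepl("^peakA", d$rep_a$name)]
  dist <- peakDistanceBetweenTFs(pa, d$tf_b)
  expect_lt(abs(dist$median - median(abs(tfbOffsets(d$truth)))), 10)
})
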