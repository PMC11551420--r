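test_that("IUPAC scanning matches consensus semantics on constructed cases", {
  aw <- motifPanel()[["AW-Box"]]
  hit <- scanMotif("CATAGAAAAAAACG", aw)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 1L)
  expect_equal(hit$strand, "+")
  expect_equal(nrow(scanMotif(strrep("A", 14), aw)), 0L)

  # an N in the sequence is matched only by the pattern code N
  expect_equal(nrow(scanMotif("CATNGAAAAAAACG", aw)), 1L)  # N at an N slot
  expect_equal(nrow(scanMotif("NATAGAAAAAAACG", aw,
                              both_strands = FALSE)), 0L)  # N at the C slot
  expect_error(scanMotif("CATXG", aw), "invalid base")
  expect_error(iupacMotif("bad", "CQT"), "IUPAC")

  # a resolved instance always matches its own motif
  set.seed(41)
  for (mo in motifPanel())
    expect_true(hasMotif(resolveIUPAC(mo), mo))
})

test_that("IUPAC scanning equals independent oracles on random sequence", {
  set.seed(42)
  panel <- c(motifPanel(), list(shortAW = shortAWBox()))
  # pure-R per-position loop oracle on short sequences
  for (i in 1:5) {
    s <- randomSeq(600, gc = 0.4)
    for (mo in panel) {
      mine <- scanMotif(s, mo)
      exp_fwd <- naiveScanOneStrand(s, motifPattern(mo))
      exp_rev <- naiveScanOneStrand(s, reverseComplementIUPAC(motifPattern(mo)))
      expect_identical(mine$start[mine$strand == "+"], exp_fwd)
      expect_identical(mine$start[mine$strand == "-"], exp_rev)
    }
  }
  # Biostrings oracle on long sequences
  for (i in 1:5) {
    s <- randomSeq(10000)
    for (mo in panel) {
      mine <- scanMotif(s, mo)
      subj <- Biostrings::DNAString(s)
      fwd <- Biostrings::start(Biostrings::matchPattern(
        motifPattern(mo), subj, fixed = "subject"))
      rev <- Biostrings::start(Biostrings::matchPattern(
        reverseComplementIUPAC(motifPattern(mo)), subj, fixed = "subject"))
      expect_identical(mine$start[mine$strand == "+"], fwd)
      expect_identical(mine$start[mine$strand == "-"], rev)
    }
  }
})

test_that("double-strand match counts are reverse-complement invariant", {
  set.seed(43)
  for (i in 1:20) {
    s <- randomSeq(2000, gc = runif(1, 0.3, 0.7))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    for (mo in motifPanel())
      expect_equal(nrow(scanMotif(s, mo)), nrow(scanMotif(rc, mo)))
  }
})

test_that("matched background preserves width and TSS offset", {
  d <- smallSim()
  offs <- c(-400L, 150L, 800L)
  bg <- sampleMatchedBackground(offs, 100L, d$models, d$genome, seed = 44L)
  expect_true(all(GenomicRanges::width(bg$regions) == 100L))
  expect_length(bg$regions, 3L)

  # with a single gene the background offset is forced to equal the site's
  one <- d$models[1]
  g1 <- geneRanges(one)
  bg1 <- sampleMatchedBackground(200L, 100L, one, d$genome, seed = 45L)
  center <- GenomicRanges::start(bg1$regions) + 50L
  expected <- if (as.character(GenomicRanges::strand(g1)) == "+")
    unname(tss(one)) + 200L else unname(tss(one)) - 200L
  expect_equal(unname(center), expected)

  # impossible placement errors out with the site index
  expect_error(sampleMatchedBackground(10000000L, 100L, one, d$genome,
                                       seed = 1L, max_attempts = 5L),
               "site 1")
})

test_that("motif enrichment computes the one-sided Fisher tail with Bonferroni", {
  aw <- motifPanel()[["AW-Box"]]
  withm <- function(n) vapply(seq_len(n), function(i)
    plantInSeqs(randomSeq(30, gc = 0), aw, 1L), character(1))
  without <- function(n) replicate(n, strrep("A", 30))  # cannot match (needs C/G)
  set.seed(46)

  # equal fractions: no signal
  eq <- motifEnrichment(c(withm(5), without(5)), c(withm(5), without(5)),
                        list(aw))
  expect_gte(eq$pvalue, 0.5)
  expect_false(eq$significant)

  # 9/1 versus 1/9: tail equals the hypergeometric enumeration
  er <- motifEnrichment(c(withm(9), without(1)), c(withm(1), without(9)),
                        list(aw))
  enum <- (choose(10, 9) * choose(10, 1) + choose(10, 10)) / choose(20, 10)
  expect_equal(er$pvalue, enum, tolerance = 1e-12)
  expect_equal(er$pvalue,
               fisher.test(matrix(c(9, 1, 1, 9), 2),
                           alternative = "greater")$p.value,
               tolerance = 1e-9)
  expect_equal(er$adjusted_pvalue, min(1, er$pvalue * 1))
  expect_error(motifEnrichment(character(), without(5), list(aw)),
               "non-empty")

  # planted 56% of 200 sites versus matched background: significant after
  # Bonferroni over the 5-motif panel
  d <- midSim()
  tab <- enrichmentRun(d$models, d$genome, seed = 47L, rate = 0.56)
  expect_true(tab$significant[tab$motif == "AW-Box"])
  expect_equal(tab$adjusted_pvalue, pmin(1, tab$pvalue * 5))
})

test_that("the random-gene-set null yields calibrated empirical p-values", {
  d <- smallSim()
  aw <- motifPanel()[["AW-Box"]]
  ids <- geneIds(d$models)

  # target set = whole universe: every background fraction ties, p = 1
  res <- genesetMotifBackground(ids, d$models, d$genome, aw,
                                n_sets = 50L, seed = 48L)
  expect_true(all(res$background_fractions == res$observed_fraction))
  expect_equal(res$empirical_p, 1)
  expect_gte(res$empirical_p, 1 / 51)

  # plant the motif downstream of 70% of a 120-gene target set and 40% of
  # the rest: the observed fraction exceeds every random set of matched size
  dm <- midSim()
  genome <- dm$genome
  mids <- geneIds(dm$models)
  set.seed(49)
  target <- sample(mids, 120)
  rest <- setdiff(mids, target)
  plant_into <- function(genome, genes, frac) {
    sel <- sample(genes, round(frac * length(genes)))
    reg <- tssRegions(dm$models[sel], genome, "downstream", 500L)
    for (i in seq_along(reg)) {
      inst <- resolveIUPAC(aw)
      pos <- GenomicRanges::start(reg)[i] + sample.int(480L, 1L)
      ch <- as.character(GenomicRanges::seqnames(reg))[i]
      genome[[ch]] <- Biostrings::replaceAt(
        genome[[ch]], IRanges::IRanges(pos, pos + 13L),
        Biostrings::DNAString(inst))
    }
    genome
  }
  genome <- plant_into(genome, target, 0.7)
  genome <- plant_into(genome, rest, 0.4)
  res2 <- genesetMotifBackground(target, dm$models, genome, aw,
                                 n_sets = 200L, seed = 50L)
  expect_gt(res2$observed_fraction, 0.6)
  expect_equal(res2$empirical_p, 1 / 201)
  expect_error(genesetMotifBackground(ids[1:3], d$models, d$genome, aw,
                                      n_sets = 0L), "n_sets")
})

test_that("motif positional distribution conserves matches and finds plants", {
  d <- smallSim()
  probe <- iupacMotif("probe", "ACGTTGCACGTA")  # 12-mer, negligible chance rate
  genome <- d$genome
  # plant the probe at strand-aware offset +200 from every TSS
  g <- geneRanges(d$models)
  plus <- as.character(GenomicRanges::strand(g)) == "+"
  tsspos <- tss(d$models)
  for (i in seq_along(g)) {
    ch <- as.character(GenomicRanges::seqnames(g))[i]
    if (plus[i]) {
      s <- tsspos[i] + 200L
      inst <- motifPattern(probe)
    } else {
      s <- tsspos[i] - 200L - 11L
      inst <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motifPattern(probe))))
    }
    genome[[ch]] <- Biostrings::replaceAt(genome[[ch]],
                                          IRanges::IRanges(s, s + 11L),
                                          Biostrings::DNAString(inst))
  }
  res <- motifPositionalDistribution(d$models, genome, probe,
                                     window = 1000L, bin_width = 100L)
  expect_equal(res$n_matches, length(d$models))
  expect_true(all(res$offsets == 200L))
  expect_equal(res$histogram$count[res$histogram$bin_start == 200],
               length(d$models))
  expect_equal(sum(res$histogram$count), res$n_matches)

  # in unplanted sequence the distribution is approximately flat
  res0 <- motifPositionalDistribution(d$models, d$genome,
                                      motifPanel()[["CCAAT-Box"]],
                                      window = 1000L, bin_width = 200L)
  expect_equal(sum(res0$histogram$count), res0$n_matches)
  cnt <- res0$histogram$count
  # expected proportional to eligible match starts per bin
  eligible <- rep(200, length(cnt))
  eligible[length(eligible)] <- 200 - motifLength(motifPanel()[["CCAAT-Box"]]) + 1
  gof <- suppressWarnings(chisq.test(cnt, p = eligible / sum(eligible)))
  expect_gt(gof$p.value, 0.01)
})
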