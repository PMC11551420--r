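# Shared fixtures (built once per test run) and independent oracles.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# small study: fast, 10% replicate noise (the generator default)
smallSim <- function() fixture("smallSim", function()
  simulateDataset(simulationConfig(seed = 101L, n_genes = 120L,
                                   n_peaks = 40L, n_chroms = 2L,
                                   chrom_length = 500000L)))

# mid-size study for distributional checks
midSim <- function() fixture("midSim", function()
  simulateDataset(simulationConfig(seed = 202L, n_genes = 600L,
                                   n_peaks = 200L, n_chroms = 2L,
                                   chrom_length = 2000000L)))

chromLengths <- function(genome)
  stats::setNames(Biostrings::width(genome), names(genome))

# ---- independent oracles ----

# naive per-position IUPAC matcher (character-level loop, one strand)
naiveScanOneStrand <- function(seq, pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N"))
  sv <- strsplit(seq, "")[[1]]
  pv <- strsplit(pattern, "")[[1]]
  hits <- integer()
  for (i in seq_len(length(sv) - length(pv) + 1)) {
    ok <- TRUE
    for (j in seq_along(pv))
      if (!sv[i + j - 1] %in% sets[[pv[j]]]) { ok <- FALSE; break }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# hypergeometric upper tail by direct summation of binomial coefficients
enumHyperUpper <- function(k, N, K, n) {
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(choose(K, k:hi) * choose(N - K, n - (k:hi))) / choose(N, n)
}

# exact two-sided Wilcoxon p by enumeration of all rank assignments
enumWilcoxP <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_along(x)])
  stats <- apply(utils::combn(n, length(x)), 2, function(ix) sum(r[ix]))
  mean(abs(stats - mean(stats)) >= abs(obs - mean(stats)) - 1e-9)
}

randomSeq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# plant a concrete instance of `motif` at a random offset of each selected
# sequence (character vector in, character vector out)
plantInSeqs <- function(seqs, motif, which_plant) {
  m <- motifLength(motif)
  for (i in which_plant) {
    inst <- resolveIUPAC(motif)
    pos <- sample.int(nchar(seqs[i]) - m + 1L, 1L)
    substr(seqs[i], pos, pos + m - 1L) <- inst
  }
  seqs
}

# one seeded motif-enrichment experiment: n_sites TSS-offset-matched
# regions with `rate` of them carrying a planted motif, versus a matched
# random background; returns the enrichment table for the standard panel
enrichmentRun <- function(models, genome, seed, rate, n_sites = 200L,
                          width = 100L) {
  set.seed(seed)
  offs <- .drawOffsets(n_sites, simulationConfig()@peak_offset_distribution)
  sites <- sampleMatchedBackground(offs, width, models, genome, seed = seed)
  seqs <- as.character(sites$seqs)
  aw <- motifPanel()[["AW-Box"]]
  planted <- which(stats::runif(n_sites) < rate)
  seqs <- plantInSeqs(seqs, aw, planted)
  bg <- sampleMatchedBackground(offs, width, models, genome,
                                seed = seed + 100000L)
  motifEnrichment(seqs, bg$seqs, motifPanel())
}

# tiny hand-written GFF3 for parser tests
writeToyGFF3 <- function(path, lines = NULL) {
  if (is.null(lines)) lines <- c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t101\t700\t.\t+\t.\tID=gA",
    "chr1\ttoy\tmRNA\t101\t700\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\ttoy\texon\t101\t300\t.\t+\t.\tID=gA.1.e1;Parent=gA.1",
    "chr1\ttoy\texon\t401\t700\t.\t+\t.\tID=gA.1.e2;Parent=gA.1",
    "chr1\ttoy\tfive_prime_UTR\t101\t150\t.\t+\t.\tID=gA.1.u5;Parent=gA.1",
    "chr1\ttoy\tgene\t1001\t1600\t.\t-\t.\tID=gB",
    "chr1\ttoy\tmRNA\t1001\t1600\t.\t-\t.\tID=gB.1;Parent=gB",
    "chr1\ttoy\texon\t1001\t1600\t.\t-\t.\tID=gB.1.e1;Parent=gB.1")
  writeLines(lines, path)
  path
}
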