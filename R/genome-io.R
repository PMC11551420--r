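#' @include gene-models.R
NULL

# ---- GFF3 ----

#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA`, `exon`, `five_prime_UTR` and `three_prime_UTR`
#' features linked by `ID`/`Parent` and collapses each gene to its
#' representative transcript (the longest mRNA; ties broken by transcript
#' id).  Malformed lines and child features with an unknown `Parent` are
#' errors.
#'
#' @param path path to a GFF3 file (1-based inclusive coordinates).
#' @return A [GeneModels-class] object, genes ordered by (chromosome, start).
#' @export
readGFF3 <- function(path) {
  raw <- readLines(path)
  body <- !startsWith(raw, "#") & nzchar(raw)
  nfield <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1L]]
    stop(sprintf("malformed GFF3 line %d in '%s': expected 9 tab-separated fields",
                 bad, path), call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(GeneModels(GRanges(gene_id = character())))

  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))

  genes <- gr[type == "gene"]
  gene_ids <- as.character(genes$ID)
  mrna <- gr[type == "mRNA"]
  if (length(mrna)) {
    mp <- parent[type == "mRNA"]
    if (any(!mp %in% gene_ids))
      stop(sprintf("mRNA with unknown Parent '%s'", mp[!mp %in% gene_ids][1L]),
           call. = FALSE)
  }
  child <- gr[type %in% c("exon", "five_prime_UTR", "three_prime_UTR")]
  if (length(child)) {
    cp <- parent[type %in% c("exon", "five_prime_UTR", "three_prime_UTR")]
    if (any(!cp %in% as.character(mrna$ID)))
      stop(sprintf("feature with unknown Parent '%s'", cp[!cp %in% as.character(mrna$ID)][1L]),
           call. = FALSE)
  }

  ord <- order(as.character(seqnames(genes)), start(genes), gene_ids)
  genes <- genes[ord]
  gene_ids <- gene_ids[ord]

  mrna_parent <- parent[type == "mRNA"]
  pickTx <- function(gid) {
    cand <- which(mrna_parent == gid)
    if (!length(cand)) return(NA_character_)
    w <- width(mrna)[cand]
    cand <- cand[w == max(w)]
    as.character(mrna$ID[cand[order(as.character(mrna$ID[cand]))[1L]]])
  }
  child_parent <- parent[type %in% c("exon", "five_prime_UTR", "three_prime_UTR")]
  child_type <- type[type %in% c("exon", "five_prime_UTR", "three_prime_UTR")]

  grabChild <- function(tx, what) {
    if (is.na(tx)) return(GRanges())
    sel <- child[child_parent == tx & child_type == what]
    GenomicRanges::granges(GenomicRanges::sort(sel, ignore.strand = TRUE))
  }

  exl <- vector("list", length(genes)); u5 <- exl; u3 <- exl
  for (i in seq_along(genes)) {
    tx <- pickTx(gene_ids[i])
    ex <- grabChild(tx, "exon")
    if (length(ex) == 0L) ex <- GenomicRanges::granges(genes[i])
    exl[[i]] <- ex
    u5[[i]] <- grabChild(tx, "five_prime_UTR")
    u3[[i]] <- grabChild(tx, "three_prime_UTR")
  }
  g <- GenomicRanges::granges(genes)
  mcols(g)$gene_id <- gene_ids
  mk <- function(l) { gl <- GRangesList(l); names(gl) <- gene_ids; gl }
  GeneModels(g, exons = mk(exl), utr5 = mk(u5), utr3 = mk(u3))
}

#' Write gene models to GFF3
#'
#' Deterministic serializer (genes ordered by chromosome then start; one
#' mRNA per gene).  `readGFF3()` followed by `writeGFF3()` round-trips
#' byte-identically.
#'
#' @param models a [GeneModels-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGFF3 <- function(models, path) {
  g <- geneRanges(models)
  ord <- order(as.character(seqnames(g)), start(g), geneIds(models))
  lines <- "##gff-version 3"
  fmt <- function(chrom, type, s, e, strand, attr)
    sprintf("%s\tTFdirect\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, s, e, strand, attr)
  for (i in ord) {
    gid <- geneIds(models)[i]
    chrom <- as.character(seqnames(g))[i]
    str <- as.character(strand(g))[i]
    tx <- paste0(gid, ".1")
    lines <- c(lines,
      fmt(chrom, "gene", start(g)[i], end(g)[i], str, paste0("ID=", gid)),
      fmt(chrom, "mRNA", start(g)[i], end(g)[i], str,
          paste0("ID=", tx, ";Parent=", gid)))
    emit <- function(grl, type, tag) {
      rg <- grl[[i]]
      if (length(rg) == 0L) return(character())
      rg <- GenomicRanges::sort(rg, ignore.strand = TRUE)
      sprintf("%s\tTFdirect\t%s\t%d\t%d\t.\t%s\t.\tID=%s.%s%d;Parent=%s",
              chrom, type, start(rg), end(rg), str, tx, tag,
              seq_along(rg), tx)
    }
    lines <- c(lines,
      emit(exonRanges(models), "exon", "exon"),
      emit(utr5Ranges(models), "five_prime_UTR", "u5."),
      emit(utr3Ranges(models), "three_prime_UTR", "u3."))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- narrowPeak ----

#' Read ChIP-Seq peaks from a narrowPeak (BED6+4) file
#'
#' Returns peaks as a `GRanges` sorted by (chromosome, start) with
#' `mcols()` columns `name`, `score`, `signalValue`, `pValue`, `qValue` and
#' `summit` (absolute 1-based position).  The summit is `start + offset`
#' when column 10 is a non-negative offset from the peak start, and the
#' interval midpoint (floor) when it is `-1`.
#'
#' @param path path to a narrowPeak file (0-based half-open coordinates).
#' @return `GRanges` of peaks.
#' @export
readNarrowPeak <- function(path) {
  first <- utils::read.table(path, sep = "\t", comment.char = "#",
                             colClasses = "character", nrows = -1)
  if (ncol(first) < 10L)
    stop("narrowPeak requires 10 columns (BED6+4)", call. = FALSE)
  if (any(as.numeric(first[[2]]) < 0))
    stop("negative start coordinate in narrowPeak file", call. = FALSE)
  gr <- rtracklayer::import(path, format = "narrowPeak")
  off <- as.integer(gr$peak)
  if (any(off >= width(gr)))
    stop("summit offset >= peak length in narrowPeak file", call. = FALSE)
  summit <- ifelse(off >= 0L, start(gr) + off,
                   start(gr) + as.integer(floor(width(gr) / 2)))
  mcols(gr)$summit <- as.integer(summit)
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write peaks to a narrowPeak file
#'
#' @param peaks `GRanges` with optional `name`, `score`, `signalValue`,
#'   `pValue`, `qValue`, `summit` metadata columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNarrowPeak <- function(peaks, path) {
  n <- length(peaks)
  getm <- function(col, default) {
    v <- mcols(peaks)[[col]]
    if (is.null(v)) rep(default, n) else v
  }
  summit <- getm("summit", NA_integer_)
  off <- ifelse(is.na(summit), -1L, as.integer(summit - start(peaks)))
  str <- as.character(strand(peaks))
  str[str == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = getm("name", "."), score = getm("score", 0),
                   strand = str,
                   signalValue = getm("signalValue", 0),
                   pValue = getm("pValue", -1), qValue = getm("qValue", -1),
                   peak = off)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- FASTA ----

#' Read a genome FASTA into a DNAStringSet
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that strips
#' description text from sequence names.
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return Named `DNAStringSet`.
#' @export
readFastaGenome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract genomic sequence for intervals
#'
#' Returns the uppercase sequence of each interval; minus-strand intervals
#' are reverse complemented.  Out-of-bounds requests are errors, never
#' silently clipped.
#'
#' @param genome named `DNAStringSet` (one entry per chromosome).
#' @param intervals `GRanges` (strand `+`, `-` or `*`; `*` is treated as `+`).
#' @return `DNAStringSet` parallel to `intervals`.
#' @export
fetchSequence <- function(genome, intervals) {
  chrom <- as.character(seqnames(intervals))
  bad <- !chrom %in% names(genome)
  if (any(bad))
    stop(sprintf("chromosome '%s' not in genome", chrom[bad][1L]), call. = FALSE)
  if (any(width(intervals) < 1L))
    stop("zero-width interval requested", call. = FALSE)
  lens <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(start(intervals) < 1L) || any(end(intervals) > lens))
    stop("interval out of chromosome bounds", call. = FALSE)
  seqs <- Biostrings::DNAStringSet(genome[chrom],
                                   start = start(intervals),
                                   end = end(intervals))
  minus <- as.character(strand(intervals)) == "-"
  if (any(minus))
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  names(seqs) <- names(intervals)
  seqs
}
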