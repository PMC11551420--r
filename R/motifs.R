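#' @include genome-io.R
NULL

# IUPAC degenerate alphabet.  A sequence 'N' is treated as unknown: it is
# matched only by the pattern code 'N' (which otherwise means "any base").
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N"))

.IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                       S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                       D = "H", H = "D", N = "N")

#' Create an IUPAC motif
#'
#' @param name motif name.
#' @param pattern consensus over the IUPAC degenerate DNA alphabet.
#' @return An [IUPACMotif-class] object.
#' @examples
#' iupacMotif("AW-Box", "CNTNGNNNNNNNCG")
#' @export
iupacMotif <- function(name, pattern) {
  new("IUPACMotif", name = as.character(name), pattern = toupper(pattern))
}

#' @rdname IUPACMotif-methods
#' @export
setMethod("motifName", "IUPACMotif", function(x) x@name)

#' @rdname IUPACMotif-methods
#' @export
setMethod("motifPattern", "IUPACMotif", function(x) x@pattern)

#' @rdname IUPACMotif-methods
#' @export
setMethod("motifLength", "IUPACMotif", function(x) nchar(x@pattern))

setMethod("show", "IUPACMotif", function(object) {
  cat(sprintf("IUPACMotif %s: %s (%d bp)\n", object@name, object@pattern,
              nchar(object@pattern)))
})

#' Reverse complement of an IUPAC pattern
#'
#' @param pattern IUPAC consensus string.
#' @return The reverse-complement consensus.
#' @export
reverseComplementIUPAC <- function(pattern) {
  paste(rev(.IUPAC_COMPLEMENT[strsplit(toupper(pattern), "")[[1]]]),
        collapse = "")
}

#' The standard motif panel
#'
#' The five known seed cis-regulatory elements screened against binding
#' sites: the gapped AW Box (`CNTNGNNNNNNNCG`), the CNC Box (`CNCCNCC`),
#' the G Box (`CACGTG`), the RY element (`CATGCA`) and the CCAAT Box.
#' `shortAWBox()` returns the abbreviated AW Box with one fewer spacer
#' position (`CNTNGNNNNNNCG`).
#'
#' @return `motifPanel()`: a named list of [IUPACMotif-class] objects.
#' @export
motifPanel <- function() {
  list(`AW-Box` = iupacMotif("AW-Box", "CNTNGNNNNNNNCG"),
       `CNC-Box` = iupacMotif("CNC-Box", "CNCCNCC"),
       `G-Box` = iupacMotif("G-Box", "CACGTG"),
       RY = iupacMotif("RY", "CATGCA"),
       `CCAAT-Box` = iupacMotif("CCAAT-Box", "CCAAT"))
}

#' @rdname motifPanel
#' @export
shortAWBox <- function() iupacMotif("short-AW-Box", "CNTNGNNNNNNCG")

#' Read a motif panel from a two-column file
#'
#' Format: `name<TAB>IUPAC` per line, `#` comments allowed.
#'
#' @param path path to the panel file.
#' @return Named list of [IUPACMotif-class] objects.
#' @export
readMotifPanel <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("name", "pattern"),
                          colClasses = "character")
  ms <- Map(iupacMotif, df$name, df$pattern)
  stats::setNames(ms, df$name)
}

# one-strand matcher: integer codes of sequence bytes, per-position lookup
.scanOneStrand <- function(sv, pattern) {
  L <- length(sv)
  chars <- strsplit(pattern, "")[[1]]
  m <- length(chars)
  if (m > L) return(integer())
  res <- NULL
  for (j in seq_len(m)) {
    allowed <- utf8ToInt(paste(.IUPAC_SETS[[chars[j]]], collapse = ""))
    ok <- sv[j:(L - m + j)] %in% allowed
    res <- if (is.null(res)) ok else res & ok
    if (!any(res)) return(integer())
  }
  which(res)
}

#' Scan a sequence for a degenerate motif
#'
#' Reports every offset at which each motif position's IUPAC base set
#' contains the sequence base.  With `both_strands = TRUE` (default) the
#' reverse-complement pattern is also matched against the same sequence and
#' reported on the `-` strand, so a match set is reverse-complement
#' invariant.  An `N` in the sequence is matched only by the pattern code
#' `N`.
#'
#' @param sequence a single character string or `DNAString` over `ACGTN`.
#' @param motif an [IUPACMotif-class] object.
#' @param both_strands scan both strands?
#' @return `data.frame` with columns `start` (1-based match start on the
#'   given sequence) and `strand`, ordered by start then strand.
#' @export
scanMotif <- function(sequence, motif, both_strands = TRUE) {
  s <- toupper(as.character(sequence))
  sv <- utf8ToInt(s)
  bad <- !sv %in% utf8ToInt("ACGTN")
  if (any(bad))
    stop(sprintf("invalid base '%s' in sequence", substr(s, which(bad)[1L],
                                                         which(bad)[1L])),
         call. = FALSE)
  fwd <- .scanOneStrand(sv, motifPattern(motif))
  hits <- data.frame(start = fwd, strand = rep("+", length(fwd)))
  if (both_strands) {
    rev <- .scanOneStrand(sv, reverseComplementIUPAC(motifPattern(motif)))
    hits <- rbind(hits, data.frame(start = rev,
                                   strand = rep("-", length(rev))))
  }
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

#' Motif membership and counts over many sequences
#'
#' `countMotifMatches()` returns the number of matches per sequence;
#' `hasMotif()` whether each sequence contains at least one match.
#'
#' @param sequences `DNAStringSet` or character vector.
#' @inheritParams scanMotif
#' @return Integer (`countMotifMatches`) or logical (`hasMotif`) vector
#'   parallel to `sequences`.
#' @export
countMotifMatches <- function(sequences, motif, both_strands = TRUE) {
  vapply(as.character(sequences), function(s)
    nrow(scanMotif(s, motif, both_strands)), integer(1), USE.NAMES = FALSE)
}

#' @rdname countMotifMatches
#' @export
hasMotif <- function(sequences, motif, both_strands = TRUE) {
  countMotifMatches(sequences, motif, both_strands) > 0L
}

#' Draw a concrete instance of a degenerate motif
#'
#' Degenerate positions are resolved uniformly over their allowed bases
#' (never to `N`), the convention also used when planting motifs in
#' synthetic genomes, which keeps chance match rates calculable.
#'
#' @inheritParams scanMotif
#' @return A single concrete DNA string matching `motif`.
#' @export
resolveIUPAC <- function(motif) {
  chars <- strsplit(motifPattern(motif), "")[[1]]
  paste(vapply(chars, function(ch) {
    bases <- setdiff(.IUPAC_SETS[[ch]], "N")
    bases[sample.int(length(bases), 1L)]
  }, character(1)), collapse = "")
}

#' Chance per-site motif match rate
#'
#' Probability that a window of `site_width` i.i.d. bases at GC fraction
#' `gc` contains at least one double-strand match of `motif`, computed from
#' the per-offset match probability under independence (a slight
#' approximation for overlapping offsets, adequate as a background
#' control).
#'
#' @inheritParams scanMotif
#' @param gc genome GC fraction.
#' @param site_width window width in bp.
#' @param both_strands count matches on both strands?
#' @return A probability.
#' @export
chanceMatchRate <- function(motif, gc = 0.5, site_width = 100,
                            both_strands = TRUE) {
  baseProb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  perOffset <- function(pattern) {
    chars <- strsplit(pattern, "")[[1]]
    prod(vapply(chars, function(ch)
      sum(baseProb[setdiff(.IUPAC_SETS[[ch]], "N")]), numeric(1)))
  }
  p <- perOffset(motifPattern(motif))
  if (both_strands) {
    fwd <- strsplit(motifPattern(motif), "")[[1]]
    rc <- strsplit(reverseComplementIUPAC(motifPattern(motif)), "")[[1]]
    # P(match on both strands at one offset): positionwise set intersection
    pBoth <- prod(vapply(seq_along(fwd), function(j)
      sum(baseProb[intersect(setdiff(.IUPAC_SETS[[fwd[j]]], "N"),
                             setdiff(.IUPAC_SETS[[rc[j]]], "N"))]),
      numeric(1)))
    p <- p + perOffset(paste(rc, collapse = "")) - pBoth
  }
  n_off <- site_width - motifLength(motif) + 1L
  if (n_off <= 0L) return(0)
  1 - (1 - p)^n_off
}
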