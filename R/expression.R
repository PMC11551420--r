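#' @include simulate.R
NULL

.countsOf <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts")
  else as.matrix(x)
}

.groupsOf <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    as.character(SummarizedExperiment::colData(x)$group)
  else NULL
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Library scaling factors from the trimmed mean of M-values: the
#' reference sample is the one whose upper quartile (of counts per library
#' size) is closest to the mean upper quartile; per sample, M (log2 ratio
#' of proportions) and A (average log2 abundance) values over genes nonzero
#' in both libraries are doubly trimmed (`trim_m` of each M tail, `trim_a`
#' of each A tail) and averaged with inverse delta-method variance weights;
#' factors are normalized to geometric mean 1.
#'
#' @param x `SummarizedExperiment` (assay `counts`) or count matrix.
#' @param trim_m,trim_a tail fractions trimmed on M and A.
#' @return Named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmmFactors <- function(x, trim_m = 0.30, trim_a = 0.05) {
  counts <- .countsOf(x)
  if (ncol(counts) < 2L) stop("need at least two samples", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample", call. = FALSE)
  uq <- apply(counts, 2L, function(y) .upperQuartile(y / sum(y)))
  ref <- which.min(abs(uq - mean(uq)))
  yr <- counts[, ref]; lr <- lib[ref]

  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    ys <- counts[, s]; ls <- lib[s]
    keep <- ys > 0 & yr > 0
    if (!any(keep)) stop("no genes shared with the reference", call. = FALSE)
    ps <- ys[keep] / ls; pr <- yr[keep] / lr
    M <- log2(ps / pr)
    A <- 0.5 * log2(ps * pr)
    w <- (ls - ys[keep]) / (ls * ys[keep]) + (lr - yr[keep]) / (lr * yr[keep])
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep2)) return(1)
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Effective library sizes under TMM
#'
#' Library size times TMM factor; the quantity a planted global scaling of
#' one library is recovered in.
#'
#' @inheritParams tmmFactors
#' @return Named numeric vector.
#' @export
effectiveLibSizes <- function(x, trim_m = 0.30, trim_a = 0.05) {
  counts <- .countsOf(x)
  colSums(counts) * tmmFactors(counts, trim_m, trim_a)
}

# two-sided conditional NB exact p: sum of conditional probabilities not
# exceeding that of the observed split (computed in log space)
.condExactP <- function(a, t, size_a, size_b) {
  if (t == 0L) return(1)
  k <- 0:t
  lp <- stats::dnbinom(k, size = size_a, mu = size_a, log = TRUE) +
    stats::dnbinom(t - k, size = size_b, mu = size_b, log = TRUE)
  lp <- lp - .logSumExp(lp)
  obs <- lp[a + 1L]
  min(1, sum(exp(lp[lp <= obs + 1e-12])))
}

#' Method-of-moments common dispersion
#'
#' Pooled across genes and groups on library-scaled counts:
#' `phi = sum (n_i - 1)(s2 - m) / sum (n_i - 1) m^2`, clipped to a small
#' positive floor.
#'
#' @param norm matrix of library-scaled counts.
#' @param group group label per column.
#' @return A single dispersion estimate.
#' @export
commonDispersion <- function(norm, group) {
  num <- 0; den <- 0
  for (gname in unique(group)) {
    sub <- norm[, group == gname, drop = FALSE]
    ni <- ncol(sub)
    if (ni < 2L) next
    m <- rowMeans(sub)
    v <- apply(sub, 1L, stats::var)
    num <- num + sum((ni - 1) * (v - m))
    den <- den + sum((ni - 1) * m^2)
  }
  max(num / den, 1e-4)
}

#' Conditional negative-binomial exact test between two groups
#'
#' Differential expression between two sample groups: counts are scaled to
#' a common effective library size (TMM-adjusted), a common dispersion is
#' estimated by the method of moments across genes, and each gene's
#' per-group sums are compared with a conditional NB exact test (the
#' conditional distribution of the group-A sum given the total, which is
#' free of the mean parameter when the groups share the dispersion).
#' Log2 fold changes use normalized group means with a 0.5 pseudo-count.
#' Genes with zero counts in both groups get p = 1 and log2fc = 0.
#'
#' @param x `SummarizedExperiment` or count matrix.
#' @param group_a,group_b sample group labels (when `x` carries
#'   `colData$group`) or column-index/name vectors.
#' @param dispersion optional fixed dispersion; estimated when `NULL`.
#' @return `data.frame(gene_id, log2fc, pvalue, fdr)` in input gene order;
#'   `fdr` is Benjamini-Hochberg.
#' @export
nbExactTest <- function(x, group_a, group_b, dispersion = NULL) {
  counts <- .countsOf(x)
  glab <- .groupsOf(x)
  pick <- function(gsel) {
    if (!is.null(glab) && all(gsel %in% glab)) which(glab %in% gsel)
    else if (is.character(gsel)) match(gsel, colnames(counts))
    else as.integer(gsel)
  }
  ia <- pick(group_a); ib <- pick(group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("need at least two replicates per group", call. = FALSE)
  sub <- counts[, c(ia, ib), drop = FALSE]
  grp <- rep(c("A", "B"), c(length(ia), length(ib)))

  eff <- effectiveLibSizes(sub)
  target <- exp(mean(log(eff)))
  norm <- sweep(sub, 2L, eff / target, "/")
  if (is.null(dispersion)) dispersion <- commonDispersion(norm, grp)

  scaled <- round(norm)
  na <- length(ia); nb <- length(ib)
  a <- as.integer(rowSums(scaled[, grp == "A", drop = FALSE]))
  b <- as.integer(rowSums(scaled[, grp == "B", drop = FALSE]))
  mean_a <- rowMeans(norm[, grp == "A", drop = FALSE])
  mean_b <- rowMeans(norm[, grp == "B", drop = FALSE])

  pv <- vapply(seq_len(nrow(sub)), function(i) {
    if (a[i] + b[i] == 0L) return(1)
    .condExactP(a[i], a[i] + b[i], na / dispersion, nb / dispersion)
  }, numeric(1))
  lfc <- ifelse(a + b == 0L, 0,
                log2(mean_a + 0.5) - log2(mean_b + 0.5))
  data.frame(gene_id = rownames(counts), log2fc = lfc, pvalue = pv,
             fdr = benjaminiHochberg(pv), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Order-preserving wrapper with input validation.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return BH q-values, parallel to the input.
#' @export
benjaminiHochberg <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' The four embryo-versus-seed-coat tissue contrasts
#'
#' Each embryo-like group against each seed-coat-like group, the contrasts
#' used to call coexpression.
#'
#' @return List of `c(group_a, group_b)` pairs.
#' @export
tissueContrasts <- function() {
  g <- tissueGroups()
  out <- list()
  for (em in g[1:2]) for (sc in g[3:4]) out[[paste(em, "vs", sc)]] <- c(em, sc)
  out
}

#' Call genes coexpressed with the factor
#'
#' A gene is coexpressed when it is at least `min_fold`-fold up-regulated
#' at FDR below `fdr_max` in at least `min_contrasts` of the supplied
#' tissue-contrast DE tables (embryo-like versus seed-coat-like).
#'
#' @param de_tables list of [nbExactTest()] result tables, one per
#'   contrast.
#' @param min_fold minimum fold change (on the natural scale).
#' @param fdr_max FDR threshold.
#' @param min_contrasts minimum number of passing contrasts.
#' @return Sorted character vector of coexpressed gene ids.
#' @export
callCoexpressed <- function(de_tables, min_fold = 2, fdr_max = 0.01,
                            min_contrasts = 2L) {
  if (length(de_tables) < min_contrasts)
    stop("fewer DE tables than min_contrasts", call. = FALSE)
  lfc_min <- log2(min_fold)
  genes <- de_tables[[1L]]$gene_id
  hits <- rowSums(vapply(de_tables, function(tab) {
    tab <- tab[match(genes, tab$gene_id), ]
    tab$log2fc >= lfc_min & tab$fdr < fdr_max
  }, logical(length(genes))))
  sort(genes[hits >= min_contrasts])
}

#' Direct target genes: bound and coexpressed
#'
#' @param bound,coexpressed gene-id character vectors over the same
#'   universe.
#' @return Their sorted intersection.
#' @export
callDirectTargets <- function(bound, coexpressed) {
  sort(intersect(bound, coexpressed))
}
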