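#' @include utils.R
NULL

#' Log-space hypergeometric upper tail
#'
#' `P(X >= k)` for `X ~ Hypergeom(N, K, n)` (population `N`, `K` marked,
#' `n` drawn), accumulated in log space for numerical safety.
#'
#' @param k observed overlap.
#' @param N,K,n hypergeometric parameters.
#' @return A probability.
#' @export
hypergeomUpperTail <- function(k, N, K, n) {
  if (k <= 0L) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- k:hi
  exp(.logSumExp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

#' Hypergeometric significance of a gene-set overlap
#'
#' Upper-tail probability of observing at least the seen overlap between
#' two sets drawn from a finite universe; the test applied to bound versus
#' coexpressed genes and to direct-target versus curated gene sets.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe the gene universe.
#' @return One-row `data.frame(n_universe, n_a, n_b, n_overlap,
#'   expected_overlap, pvalue_upper)`.
#' @export
hypergeometricOverlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    stop(sprintf("element outside universe: %s",
                 c(out_a, out_b)[1L]), call. = FALSE)
  N <- length(universe); Ka <- length(set_a); nb <- length(set_b)
  k <- length(intersect(set_a, set_b))
  data.frame(n_universe = N, n_a = Ka, n_b = nb, n_overlap = k,
             expected_overlap = Ka * nb / N,
             pvalue_upper = hypergeomUpperTail(k, N, Ka, nb))
}

#' Term (GO-style) enrichment of a gene set
#'
#' Per-term hypergeometric upper-tail p-values with Benjamini-Hochberg
#' correction across all terms represented in the universe; the term-to-
#' gene map is taken as given (no ontology propagation).
#'
#' @param gene_set character vector of genes.
#' @param term_to_genes named list mapping term ids to gene-id vectors
#'   (each a subset of `universe`).
#' @param universe the gene universe.
#' @param q_max significance threshold on the q-value.
#' @return `data.frame(term, k, K, n_set, n_universe, pvalue, qvalue,
#'   significant)`, sorted by q-value then p-value.
#' @export
termEnrichment <- function(gene_set, term_to_genes, universe, q_max = 0.01) {
  universe <- unique(universe)
  gene_set <- intersect(unique(gene_set), universe)
  rows <- lapply(names(term_to_genes), function(tm) {
    tg <- unique(term_to_genes[[tm]])
    if (length(setdiff(tg, universe)))
      stop(sprintf("term '%s' has genes outside the universe", tm),
           call. = FALSE)
    K <- length(tg)
    if (K == 0L) return(NULL)
    k <- length(intersect(tg, gene_set))
    data.frame(term = tm, k = k, K = K, n_set = length(gene_set),
               n_universe = length(universe),
               pvalue = if (length(gene_set) == 0L) 1 else
                 hypergeomUpperTail(k, length(universe), K,
                                    length(gene_set)))
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame())
  res$qvalue <- benjaminiHochberg(res$pvalue)
  res$significant <- res$qvalue < q_max
  res[order(res$qvalue, res$pvalue, res$term), , drop = FALSE]
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration p-value when the smaller sample has at most
#' `exact_max` observations and the pooled values are tie free; otherwise
#' the normal approximation with tie and continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_max sample-size boundary of the exact path.
#' @return `list(U, p, method)` with the Mann-Whitney U of `x` and the
#'   two-sided p-value.
#' @export
wilcoxonRankSum <- function(x, y, exact_max = 8L) {
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = U, p = wt$p.value,
       method = if (exact) "exact" else "normal_approximation")
}

#' Compare an expression statistic across gene groups
#'
#' Per-group summaries (n, median, quartiles) and pairwise Wilcoxon
#' rank-sum tests between all disjoint groups; groups with fewer than two
#' genes are summarized but their tests are skipped with a flag.
#'
#' @param expression named numeric vector (gene -> level).
#' @param groups named list of disjoint gene-id vectors.
#' @return `list(summaries = data.frame, tests = data.frame)`.
#' @export
compareExpressionByGroup <- function(expression, groups) {
  ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(ids)) stop("groups must be disjoint", call. = FALSE)
  vals <- lapply(groups, function(g) unname(expression[intersect(g, names(expression))]))
  summaries <- do.call(rbind, lapply(names(groups), function(nm) {
    v <- vals[[nm]]
    data.frame(group = nm, n = length(v),
               q1 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               q3 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_)
  }))
  pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    a <- vals[[pr[1L]]]; b <- vals[[pr[2L]]]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(group_a = pr[1L], group_b = pr[2L], U = NA_real_,
                        p = NA_real_, skipped = TRUE))
    w <- wilcoxonRankSum(a, b)
    data.frame(group_a = pr[1L], group_b = pr[2L], U = w$U, p = w$p,
               skipped = FALSE)
  }))
  list(summaries = summaries, tests = tests)
}
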