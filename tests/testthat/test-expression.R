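test_that("TMM factors behave on identical, scaled and random libraries", {
  set.seed(21)
  mu <- exp(runif(4000, log(5), log(500)))
  m <- sapply(1:4, function(j) rnbinom(4000, size = 5, mu = mu))
  dimnames(m) <- list(paste0("g", 1:4000), paste0("s", 1:4))

  # identical libraries: all factors 1
  ident <- m[, c(1, 1, 1)]
  colnames(ident) <- paste0("s", 1:3)
  expect_equal(unname(tmmFactors(ident)), rep(1, 3))

  # geometric mean is 1 on any input
  f <- tmmFactors(m)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)

  # a doubled library is recovered through the effective library size
  m2 <- cbind(A = m[, 1], B = m[, 1] * 2L)
  eff <- effectiveLibSizes(m2)
  expect_equal(unname(log2(eff["B"] / eff["A"])), 1, tolerance = 1e-8)

  # planted per-sample scalings in [0.25, 4] recovered within 1%
  for (s in c(4L, 2L)) {
    ms <- m; ms[, 2] <- ms[, 2] * s
    effs <- effectiveLibSizes(ms)
    base <- effectiveLibSizes(m)
    expect_equal(log2((effs[2] / effs[1]) / (base[2] / base[1])),
                 log2(s), tolerance = 0.015, ignore_attr = TRUE)
  }

  expect_error(tmmFactors(cbind(a = c(0L, 0L), b = c(1L, 2L))), "all-zero")
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(22)
  mu <- exp(runif(5000, log(5), log(500)))
  m <- sapply(1:5, function(j) rnbinom(5000, size = 5, mu = mu * runif(1, 0.5, 2)))
  dimnames(m) <- list(paste0("g", 1:5000), paste0("s", 1:5))
  f1 <- tmmFactors(m)
  f2 <- edgeR::calcNormFactors(m, method = "TMM")
  expect_lt(max(abs(log2(f1 / f2))), 0.02)
})

test_that("the conditional NB exact test has its closed-form limits and symmetries", {
  # dispersion -> 0: agrees with the conditional binomial (Poisson) test
  condBinomP <- function(a, t, na, nb) {
    pr <- dbinom(0:t, t, na / (na + nb))
    min(1, sum(pr[pr <= pr[a + 1] + 1e-12]))
  }
  for (case in list(c(30L, 100L), c(0L, 10L), c(55L, 60L))) {
    p_nb <- .condExactP(case[1], case[2], 3 / 1e-8, 3 / 1e-8)
    expect_lt(abs(p_nb - condBinomP(case[1], case[2], 3, 3)), 1e-6)
  }

  set.seed(23)
  m <- sapply(1:6, function(j) rnbinom(300, size = 10, mu = 100))
  m[1, ] <- 0L  # all-zero gene
  dimnames(m) <- list(paste0("g", 1:300), paste0("s", 1:6))
  de_ab <- nbExactTest(m, 1:3, 4:6)
  de_ba <- nbExactTest(m, 4:6, 1:3)
  expect_equal(de_ab$pvalue, de_ba$pvalue, tolerance = 1e-12)
  expect_equal(de_ab$log2fc, -de_ba$log2fc, tolerance = 1e-12)
  expect_equal(de_ab$pvalue[1], 1)
  expect_equal(de_ab$log2fc[1], 0)
  expect_error(nbExactTest(m, 1, 2:6), "replicates")
})

test_that("the NB exact test is calibrated under the null and powered at 4-fold", {
  set.seed(24)
  n <- 500
  mu <- exp(runif(n, log(100), log(1000)))
  m <- sapply(1:6, function(j) rnbinom(n, size = 10, mu = mu))
  dimnames(m) <- list(paste0("g", 1:n), paste0("s", 1:6))
  de <- nbExactTest(m, 1:3, 4:6)
  # type-I error at alpha = 0.05: generous binomial bounds at n = 500
  expect_gt(mean(de$pvalue < 0.05), 0.02)
  expect_lt(mean(de$pvalue < 0.05), 0.09)

  fc <- c(rep(4, 100), rep(1, 400))
  m2 <- cbind(sapply(1:3, function(j) rnbinom(n, size = 10, mu = 100 * fc)),
              sapply(1:3, function(j) rnbinom(n, size = 10, mu = 100)))
  dimnames(m2) <- list(paste0("g", 1:n), paste0("s", 1:6))
  de2 <- nbExactTest(m2, 1:3, 4:6)
  expect_gte(mean(de2$fdr[1:100] < 0.05), 0.9)
})

test_that("the NB exact test ranks genes like the edgeR reference", {
  skip_if_not_installed("edgeR")
  set.seed(25)
  fc <- c(rep(3, 60), rep(1, 240))
  m <- cbind(sapply(1:3, function(j) rnbinom(300, size = 10, mu = 100 * fc)),
             sapply(1:3, function(j) rnbinom(300, size = 10, mu = 100)))
  dimnames(m) <- list(paste0("g", 1:300), paste0("s", 1:6))
  de <- nbExactTest(m, 1:3, 4:6)
  y <- edgeR::DGEList(m, group = rep(c("A", "B"), each = 3))
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateCommonDisp(y)
  et <- edgeR::exactTest(y, pair = c("B", "A"))
  expect_gt(cor(log(de$pvalue + 1e-300), log(et$table$PValue + 1e-300),
                method = "spearman"), 0.9)
})

test_that("Benjamini-Hochberg matches the hand step-up computation", {
  expect_equal(benjaminiHochberg(0.03), 0.03)
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  set.seed(26)
  p <- runif(100)
  q <- benjaminiHochberg(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p-rank
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("coexpression calling applies the at-least-two-contrasts rule", {
  mkTab <- function(lfc, fdr)
    data.frame(gene_id = paste0("g", seq_along(lfc)), log2fc = lfc,
               pvalue = fdr, fdr = fdr)
  # g1 passes in one contrast only; g2 passes in two
  tabs <- list(
    mkTab(c(2, 2), c(0.001, 0.001)),
    mkTab(c(0, 2), c(0.5, 0.001)),
    mkTab(c(0, 0), c(0.5, 0.5)),
    mkTab(c(0, 0), c(0.5, 0.5)))
  expect_identical(callCoexpressed(tabs), "g2")
  expect_error(callCoexpressed(tabs[1], min_contrasts = 2L), "fewer")

  # monotonicity: relaxing thresholds never shrinks the called set
  set.seed(27)
  rtabs <- lapply(1:4, function(i)
    mkTab(rnorm(200, 0.8, 0.8), runif(200, 0, 0.05)))
  strict <- callCoexpressed(rtabs, min_fold = 2, fdr_max = 0.01)
  relaxed_fdr <- callCoexpressed(rtabs, min_fold = 2, fdr_max = 0.05)
  relaxed_fold <- callCoexpressed(rtabs, min_fold = 1.5, fdr_max = 0.01)
  expect_true(all(strict %in% relaxed_fdr))
  expect_true(all(strict %in% relaxed_fold))
})

test_that("direct targets are the exact bound/coexpressed intersection", {
  expect_identical(callDirectTargets(c("a", "b"), c("c", "d")), character())
  expect_identical(callDirectTargets(c("a", "b", "c"), c("b", "c")),
                   c("b", "c"))
  d <- smallSim()
  tabs <- lapply(tissueContrasts(), function(ct)
    nbExactTest(d$se, ct[1], ct[2]))
  cx <- callCoexpressed(tabs)
  # planted 4-fold at n = 3: precision and recall both >= 0.9
  expect_gte(mean(cx %in% coexpressedGenes(d$truth)), 0.9)
  expect_gte(mean(coexpressedGenes(d$truth) %in% cx), 0.9)
})
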