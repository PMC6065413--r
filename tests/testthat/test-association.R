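test_that("gap split picks the maximal successive gap", {
  f <- setNames(c(0.00, 0.01, 0.50, 0.60), paste0("t", 1:4))
  s <- gapSplit(f)
  expect_equal(sort(s$group1), c("t1", "t2"))
  expect_equal(sort(s$group2), c("t3", "t4"))
  expect_equal(s$gap, 0.49)

  two <- gapSplit(setNames(c(0, 1), c("lo", "hi")))
  expect_equal(two$group1, "lo")
  expect_equal(two$group2, "hi")

  expect_null(gapSplit(setNames(rep(0.1, 3), paste0("t", 1:3))))
})

test_that("gap split equals brute-force enumeration on small instances", {
  set.seed(12)
  for (i in 1:200) {
    nT <- sample(2:12, 1)
    f <- setNames(sample(0:20, nT, replace = TRUE) / 20, paste0("t", 1:nT))
    b <- bruteGapSplit(f)
    s <- gapSplit(f)
    if (is.null(b)) {
      expect_null(s)
    } else {
      expect_setequal(s$group1, b$group1)
      expect_setequal(s$group2, b$group2)
      expect_equal(s$gap, b$gap)
    }
  }
})

test_that("association statistic is the group-2 minus group-1 median", {
  v <- setNames(c(1, 2, 3, 4, 5, 6), paste0("t", 1:6))
  sp <- list(group1 = paste0("t", 1:3), group2 = paste0("t", 4:6))
  expect_equal(associationStatistic(v, sp), 3)
  same <- setNames(rep(2, 4), paste0("t", 1:4))
  expect_equal(associationStatistic(same,
    list(group1 = c("t1", "t2"), group2 = c("t3", "t4"))), 0)
  # chromatin-style arithmetic
  freqs <- setNames(c(0.2, 0.4, 0.0, 0.0), paste0("t", 1:4))
  expect_equal(associationStatistic(freqs,
    list(group1 = c("t3", "t4"), group2 = c("t1", "t2"))), 0.3)
})

test_that("permutation association flags degenerate inputs and finds signal", {
  freqs <- setNames(c(0.01, 0.02, 0.01, 0.0, 0.31, 0.29, 0.02, 0.01,
                      0.30, 0.32, 0.01, 0.33), paste0("t", 1:12))
  # constant feature: statistic 0, p ~ 1
  flatFeat <- setNames(rep(2, 12), paste0("t", 1:12))
  r0 <- permutationAssociation(flatFeat, freqs, nPerm = 500, seed = 1)
  expect_equal(r0$statistic, 0)
  expect_gt(r0$p, 0.9)

  # feature = the frequencies themselves, two isolated high tissues: the
  # only null assignment as extreme as the data is the high pair itself,
  # so p approaches 1/C(12,2) = 1/66 (the resolution floor of the test)
  sep <- setNames(c(0.01, 0.02, 0.01, 0.0, 0.01, 0.02, 0.02, 0.01,
                    0.01, 0.32, 0.01, 0.33), paste0("t", 1:12))
  r1 <- permutationAssociation(sep, sep, nPerm = 1e4, seed = 2)
  # expectation 1/66 with Monte-Carlo noise (sd ~ 0.0012 at 1e4 perms)
  expect_lte(r1$p, 1 / 66 + 4 * 0.0012)
  expect_gte(r1$p, 1 / 66 - 4 * 0.0012)
  expect_equal(r1$direction, "positive")

  # no-split genes are excluded with a flag
  r2 <- permutationAssociation(flatFeat,
    setNames(rep(0.1, 12), paste0("t", 1:12)), nPerm = 500)
  expect_equal(r2$flags, "no-split")
})

test_that("fast null equals the literal frequency-permutation null (5 tissues)", {
  set.seed(5)
  tissues <- paste0("t", 1:5)
  freqs <- setNames(c(0.01, 0.03, 0.10, 0.42, 0.45), tissues)
  feat <- setNames(rnorm(5), tissues)
  sp <- gapSplit(freqs)
  m <- length(sp$group2)

  # literal null: permute the frequencies over tissues, re-derive the split,
  # recompute the median feature difference
  perms <- allPerms(5)
  literal <- apply(perms, 1, function(ix) {
    fr <- setNames(freqs[ix], tissues)
    s <- gapSplit(fr)
    median(feat[s$group2]) - median(feat[s$group1])
  })
  # fast null: every m-subset of tissues as group 2, weighted equally
  combos <- combn(5, m)
  fast <- apply(combos, 2, function(g2) {
    median(feat[tissues[g2]]) - median(feat[tissues[-g2]])
  })
  expect_equal(sort(unique(round(literal, 12))),
               sort(unique(round(fast, 12))))
  # equal distribution: each subset appears the same number of times
  expect_equal(unname(table(round(literal, 12))),
               unname(table(rep(round(fast, 12), each = nrow(perms) /
                                  ncol(combos)))))
})

test_that("per-gene seeding makes results independent of gene order", {
  set.seed(6)
  genes <- paste0("g", 1:8); tissues <- paste0("t", 1:8)
  f <- namedMat(sample(0:30, 64, replace = TRUE) / 100, genes, tissues)
  fm <- namedMat(rnorm(64), genes, tissues)
  a <- associateFeature(tinyFreq(f), fm, nPerm = 300, seed = 11)
  b <- associateFeature(tinyFreq(f), fm[rev(genes), ], nPerm = 300,
                        seed = 11)
  b <- b[match(a$gene, b$gene), ]
  expect_equal(a$p, b$p)
  expect_equal(a$statistic, b$statistic)
})

test_that("direction calls follow sign at significance", {
  set.seed(9)
  genes <- paste0("g", 1:30); tissues <- paste0("t", 1:10)
  f <- namedMat(sample(0:30, 300, replace = TRUE) / 100, genes, tissues)
  fm <- namedMat(rnorm(300), genes, tissues)
  res <- associateFeature(tinyFreq(f), fm, nPerm = 300, alpha = 0.1,
                          seed = 2)
  ok <- !is.na(res$p)
  expect_true(all(ifelse(res$p[ok] < 0.1 & res$statistic[ok] != 0,
                         res$direction[ok] == ifelse(res$statistic[ok] > 0,
                                                     "positive", "negative"),
                         res$direction[ok] == "none")))
})

test_that("FDR estimate is ~1 on null data, small on planted data, flagged when empty", {
  set.seed(14)
  genes <- sprintf("g%03d", 1:200); tissues <- paste0("t", 1:12)
  f <- namedMat(rbinom(200 * 12, 100, 0.02) / 100, genes, tissues)
  fm <- namedMat(rnorm(200 * 12), genes, tissues)
  freq <- tinyFreq(f)
  res <- associateFeature(freq, fm, nPerm = 500, seed = 3)
  est <- estimateFdr(freq, fm, res, nLabelPerm = 20, nPerm = 500, seed = 4)
  nSig <- est$nSignificantEmpirical
  if (nSig > 0) {
    # both numerator and denominator estimate the same null rate
    se <- 2 / sqrt(max(1, est$nSignificantPermuted))
    expect_lt(abs(est$fdr - 1), max(0.75, 2 * se))
  }

  # strongly planted: high group carries a huge feature shift
  f2 <- namedMat(rep(c(rep(0.01, 6) + (0:5) * 0.002, rep(0.4, 6) +
                         (0:5) * 0.002), 50), sprintf("p%03d", 1:50),
                 tissues)
  fm2 <- namedMat(rep(c(rep(0, 6), rep(10, 6)), 50) + rnorm(600, 0, 0.1),
                  sprintf("p%03d", 1:50), tissues)
  freq2 <- tinyFreq(round(f2 * 100) / 100)
  res2 <- associateFeature(freq2, fm2, nPerm = 2000, seed = 5)
  expect_gt(sum(res2$p < 0.03), 40)
  est2 <- estimateFdr(freq2, fm2, res2, nLabelPerm = 10, nPerm = 2000,
                      seed = 6)
  expect_lt(est2$fdr, 0.2)

  # nothing significant -> undefined
  none <- res; none$p <- 0.9
  expect_match(estimateFdr(freq, fm, none, nPerm = 100)$flag, "undefined")
})

test_that("feature summaries compute the documented fractions", {
  mk <- function(n, nsig) data.frame(gene = sprintf("g%04d", 1:n),
    feature = "f", statistic = 1, p = c(rep(0.001, nsig),
                                        rep(0.5, n - nsig)),
    direction = "positive", nGroup1 = 1, nGroup2 = 1, flag = "")
  expect_equal(round(summarizeFeature(mk(91, 11))$fractionSignificant, 4),
               0.1209)
  expect_equal(round(summarizeFeature(mk(432, 98))$fractionSignificant, 4),
               0.2269)
  s0 <- summarizeFeature(mk(10, 0))
  expect_equal(s0$fractionSignificant, 0)
  expect_true(is.na(s0$positiveFraction))
  # gene-class cross-tabulation
  res <- mk(20, 5)
  cls <- data.frame(gene = res$gene[1:10],
                    class = rep(c("oncogene", "tsg"), 5))
  tab <- attr(summarizeFeature(res, geneClasses = cls), "classTable")
  expect_equal(sum(tab), 5)
})
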