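test_that("gene ranking is ascending with lexicographic ties", {
  p <- c(g1 = 0.5, g2 = 0.01, g3 = 0.2)
  rk <- rankGenes(p, c("g2"))
  expect_equal(rk@genes, c("g2", "g3", "g1"))

  tie <- c(BRAF = 0.01, APC = 0.01, ZZZ = 0.5)
  expect_equal(rankGenes(tie, "APC")@genes[1:2], c("APC", "BRAF"))

  # member outside the universe is dropped from K
  rk2 <- rankGenes(p, c("g2", "notHere"))
  expect_equal(sum(rk2@member), 1)
  expect_error(rankGenes(p, "absent"), "intersect")
})

test_that("observed walk counts members cumulatively and conserves K", {
  p <- setNames(seq(0.01, 0.2, length.out = 10), paste0("g", 1:10))
  top <- rankGenes(p, paste0("g", 1:3))
  w <- observedWalk(top)
  expect_equal(walkY(w), c(pmin(1:3, 3), rep(3, 7)))
  bottom <- rankGenes(p, paste0("g", 8:10))
  expect_equal(walkY(observedWalk(bottom)), c(rep(0, 7), 1:3))
  expect_equal(walkY(w)[10], 3)
})

test_that("expected walk equals the hypergeometric mean line", {
  w <- expectedWalk(10, 4, method = "pmf")
  expect_equal(walkY(w)[5], 2.0, tolerance = 1e-12)
  expect_equal(walkY(w)[10], 4)
  set.seed(2)
  for (i in 1:10) {
    N <- sample(2:60, 1); K <- sample(seq_len(N), 1)
    expect_lt(max(abs(walkY(expectedWalk(N, K, "pmf")) -
                      seq_len(N) * K / N)), 1e-9)
  }
})

test_that("extra-gene and extra-member pmfs match enumeration and normalize", {
  # Eq for new genes: N=4, n=2 -> 1/6, 2/3, 1/6
  expect_equal(extraGenesPmf(4, 2, 0), 1 / 6)
  expect_equal(extraGenesPmf(4, 2, 1), 2 / 3)
  expect_equal(extraGenesPmf(4, 2, 2), 1 / 6)
  expect_equal(extraGenesPmf(10, 0, 0), 1)
  for (N in c(5, 9, 13, 30)) for (n in 0:N) {
    support <- 0:min(n, N - n)
    expect_equal(sum(vapply(support, function(x) extraGenesPmf(N, n, x), 0)),
                 1, tolerance = 1e-12)
  }
  # exhausted member set
  expect_equal(extraCancerPmf(10, 3, 5, 3, 2, 0), 1)
  # N=6, K=2, n=2, k=1: pool of 4 genes holds 1 member
  for (kx in 0:2)
    expect_equal(extraCancerPmf(6, 2, 2, 1, 2, kx), enumHyper(4, 1, 2, kx))
  sums <- sum(vapply(0:2, function(kx) extraCancerPmf(6, 2, 2, 1, 2, kx), 0))
  expect_equal(sums, 1)
})

test_that("conditional walk closed form equals the literal double sum", {
  set.seed(7)
  p <- setNames(runif(40), sprintf("g%02d", 1:40))
  rk <- rankGenes(p, sample(names(p), 8))
  w <- observedWalk(rk)
  closed <- conditionalWalk(w, method = "closed")
  pmf <- conditionalWalk(w, method = "pmf")
  expect_equal(walkY(closed), walkY(pmf), tolerance = 1e-10)
  # no extra possible once k(n) = K; terminal equals K
  expect_equal(walkY(closed)[40], 8)
  expect_true(all(walkY(closed) >= walkY(w) - 1e-12))
})

test_that("conditional walk matches a Monte-Carlo union oracle", {
  set.seed(15)
  N <- 60; K <- 12
  p <- setNames(runif(N), sprintf("g%02d", 1:N))
  members <- sample(names(p), K)
  p[members[1:6]] <- p[members[1:6]] / 20 # informative F1
  rk <- rankGenes(p, members)
  cond <- conditionalWalk(observedWalk(rk), method = "closed")
  r1 <- match(rk@genes[rk@member], rk@genes)
  nrep <- 2000
  counts <- matrix(0, nrep, N)
  for (i in seq_len(nrep)) {
    r2 <- sample.int(N, K)
    counts[i, ] <- cumsum(tabulate(pmin(r1, r2), N))
  }
  mc <- colMeans(counts)
  se <- apply(counts, 2, sd) / sqrt(nrep)
  expect_true(all(abs(walkY(cond) - mc) <= 3 * se + 1e-9))
})

test_that("joint walk is the union count and dominates both univariates", {
  p1 <- c(a = 0.01, b = 0.4, c = 0.2, d = 0.3)
  p2 <- c(a = 0.5, b = 0.01, c = 0.2, d = 0.3)
  r1 <- rankGenes(p1, c("a", "b"))
  r2 <- rankGenes(p2, c("a", "b"))
  jw <- jointWalk(r1, r2)
  expect_equal(walkY(jw)[1], 2) # a tops list1, b tops list2
  # copy: joint equals the univariate walk
  r1copy <- rankGenes(p1, c("a", "b"))
  expect_equal(walkY(jointWalk(r1, r1copy)), walkY(observedWalk(r1)))
  # union bound, random instances
  set.seed(3)
  for (i in 1:10) {
    pp1 <- setNames(runif(20), sprintf("g%02d", 1:20))
    pp2 <- setNames(runif(20), names(pp1))
    mem <- sample(names(pp1), 5)
    a <- rankGenes(pp1, mem); b <- rankGenes(pp2, mem)
    expect_true(all(walkY(jointWalk(a, b)) >=
                    pmax(walkY(observedWalk(a)), walkY(observedWalk(b)))))
    expect_true(all(diff(c(0, walkY(jointWalk(a, b)))) %in% 0:2))
  }
  # universe mismatch is a hard error
  pp3 <- setNames(runif(10), sprintf("x%02d", 1:10))
  expect_error(jointWalk(r1, rankGenes(pp3, names(pp3)[1])), "universe")
})

test_that("walk p-values separate enrichment from null", {
  set.seed(9)
  N <- 100; K <- 10
  genes <- sprintf("g%03d", 1:N)
  # all members on top
  pTop <- setNames(seq_len(N) / N, genes)
  rkTop <- rankGenes(pTop, genes[1:K])
  pv <- walkPvalue(observedWalk(rkTop), expectedWalk(N, K), nPerm = 1e4,
                   seed = 4)
  expect_lte(pv$p, 0.01)
  # observed equal to reference: clearly not significant
  flat <- new("WalkCurve", x = seq_len(N), y = seq_len(N) * K / N,
              kind = "observed", N = as.integer(N), K = as.integer(K),
              k = seq_len(N) * K / N)
  pvSame <- walkPvalue(flat, expectedWalk(N, K), nPerm = 2000, seed = 5)
  expect_gte(pvSame$p, 0.3)
  # permuted membership: p roughly uniform
  ps <- vapply(1:60, function(i) {
    rk <- rankGenes(pTop, sample(genes, K))
    walkPvalue(observedWalk(rk), expectedWalk(N, K), nPerm = 400,
               seed = i)$p
  }, 0)
  expect_gt(mean(ps), 0.3)
  expect_gt(min(ps), 0.001)
})

test_that("bivariate classification follows the rule table and scenarios", {
  expect_equal(classifyBivariate(0.001, 0.001, 0.05), "both indispensable")
  expect_equal(classifyBivariate(0.001, 0.5, 0.05), "F2 superior")
  expect_equal(classifyBivariate(0.5, 0.001, 0.05), "F1 superior")
  expect_equal(classifyBivariate(0.5, 0.5, 0.05), "neither/overlapped")

  set.seed(31)
  genes <- sprintf("g%03d", 1:150)
  members <- sample(genes, 25)
  mkRank <- function(informative, seed, feat) {
    set.seed(seed)
    p <- setNames(runif(length(genes)), genes)
    if (informative) p[members] <- rbeta(length(members), 0.25, 1)
    rankGenes(p, members, feat)
  }
  tally <- sapply(1:10, function(i) {
    f1 <- mkRank(TRUE, 100 + i, "F1")
    copy <- rankGenes(setNames(f1@p, f1@genes), members, "F2")
    ind <- mkRank(TRUE, 500 + i, "F2")
    nul <- mkRank(FALSE, 900 + i, "F2")
    c(bivariateGsea(f1, copy, members, nPerm = 400, seed = i)$outcome,
      bivariateGsea(f1, ind, members, nPerm = 400, seed = i)$outcome,
      bivariateGsea(f1, nul, members, nPerm = 400, seed = i)$outcome)
  })
  expect_gte(mean(tally[1, ] == "neither/overlapped"), 0.8)
  expect_gte(mean(tally[2, ] == "both indispensable"), 0.8)
  expect_gte(mean(tally[3, ] == "F1 superior"), 0.7)
})
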