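## Univariate and bivariate gene-set enrichment random walks over
## association-ranked genes, with hypergeometric expected/conditional curves
## and Mann-Whitney permutation p-values.

#' Rank genes by association p-value with gene-set membership flags
#'
#' @param p named numeric vector of association p-values (one per gene in
#'   the feature's universe); NAs are dropped.
#' @param geneSet character vector of gene-set members; membership is taken
#'   as the intersection with the universe.
#' @param feature feature name carried in the ranking.
#' @return a [RankedList-class] (ascending p, ties broken lexicographically
#'   by gene symbol).
#' @export
rankGenes <- function(p, geneSet, feature = "feature") {
  p <- p[!is.na(p)]
  stopIfNot(length(p) > 0, "empty universe")
  ord <- order(p, names(p))
  genes <- names(p)[ord]
  member <- genes %in% geneSet
  stopIfNot(sum(member) >= 1, "gene set does not intersect the universe")
  new("RankedList", genes = genes, p = unname(p[ord]), member = member,
      feature = feature)
}

#' Observed enrichment random walk
#'
#' y(x) counts gene-set members among the top-x ranked genes; increments by
#' 1 at member ranks.
#'
#' @param ranked a [RankedList-class].
#' @return a [WalkCurve-class] of kind "observed" (the `k` trace equals y).
#' @export
observedWalk <- function(ranked) {
  N <- length(ranked@genes)
  y <- cumsum(as.numeric(ranked@member))
  new("WalkCurve", x = seq_len(N), y = y, kind = "observed",
      N = as.integer(N), K = as.integer(sum(ranked@member)), k = y)
}

#' Expected enrichment walk under the uninformative null
#'
#' The expected member count among n uniformly chosen top genes,
#' \eqn{\sum_k P_{n,k} k} with hypergeometric \eqn{P_{n,k}}; equals the
#' straight line nK/N (hypergeometric mean identity).
#'
#' @param N universe size.
#' @param K gene-set size (0 < K <= N).
#' @param method "closed" (nK/N) or "pmf" (the explicit sum; identical to
#'   1e-9, kept for verification).
#' @return a [WalkCurve-class] of kind "expected".
#' @export
expectedWalk <- function(N, K, method = c("closed", "pmf")) {
  method <- match.arg(method)
  stopIfNot(K >= 1 && K <= N, "need 0 < K <= N")
  n <- seq_len(N)
  y <- if (method == "closed") n * K / N else
    vapply(n, function(nn) {
      k <- 0:min(nn, K)
      sum(dhyper(k, K, N - K, nn) * k)
    }, 0)
  new("WalkCurve", x = as.integer(n), y = y, kind = "expected",
      N = as.integer(N), K = as.integer(K), k = numeric(0))
}

# curve -> pmf of the implied rank-valued random variable (normalize the
# curve by its terminal value and difference it)
curvePmf <- function(y) {
  terminal <- y[length(y)]
  stopIfNot(terminal > 0, "reference curve identically zero")
  diff(c(0, y)) / terminal
}

# Mann-Whitney statistic between two normalized curves treated as CDFs:
# theta = P(X_a < X_b) + 0.5 P(X_a = X_b), X ~ pmf of each curve.
# theta > 0.5 when curve a puts its mass at lower ranks (positive deviation).
curveTheta <- function(ya, yb) {
  pa <- curvePmf(ya)
  qb <- curvePmf(yb)
  Qb <- cumsum(qb)
  sum(pa * (1 - Qb + 0.5 * qb))
}

#' Permutation p-value for the deviation of an observed walk from a
#' reference walk
#'
#' Both curves are normalized by their terminal values and treated as CDFs
#' of rank-valued random variables; the Mann-Whitney statistic is computed
#' in closed form from the two CDFs. The null re-walks the observed curve
#' with gene-set membership permuted uniformly over ranks; the p-value is
#' the pseudocount fraction of permuted statistics at least as large as the
#' empirical one (one-sided toward positive deviation).
#'
#' @param observed a [WalkCurve-class] (kind "observed" or "joint").
#' @param reference a [WalkCurve-class] on the same rank axis.
#' @param nPerm permutations (default 1e5).
#' @param seed integer seed.
#' @return list: `p`, `theta`, `nPerm`.
#' @export
walkPvalue <- function(observed, reference, nPerm = 1e5, seed = 1) {
  stopIfNot(observed@N == reference@N, "curves on different rank axes")
  N <- observed@N
  K <- observed@K
  stopIfNot(K >= 1, "K must be >= 1")
  thetaEmp <- curveTheta(observed@y, reference@y)
  refY <- reference@y
  nullTheta <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
    ranks <- sample.int(N, K)
    y <- cumsum(tabulate(ranks, N))
    curveTheta(y, refY)
  }, 0))
  list(p = permPvalue(sum(nullTheta >= thetaEmp - 1e-12), nPerm),
       theta = thetaEmp, nPerm = as.integer(nPerm))
}

# restrict a RankedList to a shared universe, re-sorting with the tie rule
restrictRanking <- function(ranked, universe, geneSet) {
  keep <- ranked@genes %in% universe
  p <- setNames(ranked@p[keep], ranked@genes[keep])
  rankGenes(p, geneSet, feature = ranked@feature)
}

#' Joint enrichment walk over two rankings
#'
#' y(x) counts gene-set members in the union of the top-x genes of the two
#' rankings; a member enters at the smaller of its two ranks, so increments
#' are in \{0, 1, 2\}.
#'
#' @param ranked1,ranked2 [RankedList-class] objects on an identical
#'   universe with an identical member set.
#' @return a [WalkCurve-class] of kind "joint".
#' @export
jointWalk <- function(ranked1, ranked2) {
  stopIfNot(setequal(ranked1@genes, ranked2@genes),
            "rankings must share one universe (harmonize first)")
  stopIfNot(setequal(ranked1@genes[ranked1@member],
                     ranked2@genes[ranked2@member]),
            "rankings must share one gene set")
  N <- length(ranked1@genes)
  members <- ranked1@genes[ranked1@member]
  r1 <- match(members, ranked1@genes)
  r2 <- match(members, ranked2@genes)
  entry <- pmin(r1, r2)
  y <- cumsum(tabulate(entry, N))
  new("WalkCurve", x = seq_len(N), y = as.numeric(y), kind = "joint",
      N = as.integer(N), K = as.integer(length(members)), k = numeric(0))
}

#' Probability of n_extra new genes contributed by a random second ranking
#'
#' The probability that the top n genes of an uninformative second list add
#' exactly `nExtra` genes beyond the top n of the first list:
#' C(N-n, nExtra) C(n, n-nExtra) / C(N, n) (hypergeometric).
#'
#' @param N universe size; `n` rank; `nExtra` number of new genes.
#' @param n,nExtra scalars.
#' @return probability (0 outside the support).
#' @export
extraGenesPmf <- function(N, n, nExtra) {
  if (n < 0 || n > N || nExtra < 0 || nExtra > min(n, N - n)) return(0)
  if (n == 0) return(as.numeric(nExtra == 0))
  dhyper(nExtra, N - n, n, n)
}

#' Probability of k_extra gene-set members among the n_extra new genes
#'
#' Conditioned on `nExtra` new genes drawn from the N-n genes outside the
#' first list's top n (which hold K-k remaining members):
#' C(K-k, kExtra) C(N-n-K+k, nExtra-kExtra) / C(N-n, nExtra).
#'
#' @param N,K universe and set sizes; `n`,`k` the first list's rank and
#'   member count; `nExtra`,`kExtra` the added genes and members.
#' @return probability (0 outside the support).
#' @export
extraCancerPmf <- function(N, K, n, k, nExtra, kExtra) {
  if (kExtra < 0 || kExtra > min(nExtra, K - k)) return(0)
  if (nExtra - kExtra > N - n - K + k) return(0)
  if (nExtra == 0) return(as.numeric(kExtra == 0))
  dhyper(kExtra, K - k, N - n - K + k, nExtra)
}

#' Conditional enrichment walk: expected joint count when the second
#' feature is uninformative
#'
#' Given the first feature's observed member trace k(n), the curve is
#' k(n) plus the expected number of extra members contributed by the top n
#' genes of a uniformly random second ranking (double hypergeometric
#' expectation over `nExtra` and `kExtra`). The closed form
#' k(n) + (K - k(n)) n / N equals the double sum exactly (hypergeometric
#' mean identities) and is used on hot paths.
#'
#' @param f1Walk observed [WalkCurve-class] of the first feature (its `k`
#'   trace is the conditioning information).
#' @param method "closed" or "pmf" (literal double sum).
#' @return a [WalkCurve-class] of kind "conditional"; pointwise >= the
#'   first feature's walk.
#' @export
conditionalWalk <- function(f1Walk, method = c("closed", "pmf")) {
  method <- match.arg(method)
  stopIfNot(length(f1Walk@k) == f1Walk@N, "f1 walk lacks its (n, k) trace")
  N <- f1Walk@N
  K <- f1Walk@K
  k <- f1Walk@k
  n <- seq_len(N)
  y <- if (method == "closed") {
    k + (K - k) * n / N
  } else {
    vapply(n, function(nn) {
      kk <- k[nn]
      if (nn == N) return(as.numeric(kk))
      extra <- 0
      for (nx in 0:min(nn, N - nn)) {
        pn <- extraGenesPmf(N, nn, nx)
        if (pn == 0) next
        kxs <- 0:min(nx, K - kk)
        pk <- vapply(kxs, function(kx)
          extraCancerPmf(N, K, nn, kk, nx, kx), 0)
        extra <- extra + pn * sum(pk * kxs)
      }
      kk + extra
    }, 0)
  }
  new("WalkCurve", x = as.integer(n), y = y, kind = "conditional",
      N = as.integer(N), K = as.integer(K), k = k)
}

#' Classify a bivariate enrichment comparison
#'
#' @param pF2Adds p-value of the joint walk deviating positively from the
#'   conditional walk F2|F1 (does F2 add information beyond F1?).
#' @param pF1Adds the reciprocal p-value (joint vs F1|F2).
#' @param alpha significance level.
#' @return one of "both indispensable", "F2 superior", "F1 superior",
#'   "neither/overlapped".
#' @export
classifyBivariate <- function(pF2Adds, pF1Adds, alpha = 0.05) {
  sig2 <- pF2Adds < alpha
  sig1 <- pF1Adds < alpha
  if (sig2 && sig1) "both indispensable"
  else if (sig2) "F2 superior"
  else if (sig1) "F1 superior"
  else "neither/overlapped"
}

#' Bivariate gene-set enrichment analysis for two feature rankings
#'
#' Harmonizes the two rankings to the genes scored by both features
#' (recomputing the member set within the shared universe), builds the
#' joint walk and both conditional walks, and evaluates both one-sided
#' Mann-Whitney permutation p-values. The null for "does F2 add
#' information beyond F1" keeps F1's observed ranking and membership fixed
#' and replaces F2 by a uniformly random ranking (whose expected joint
#' count is exactly the conditional curve F2|F1); the reciprocal test
#' permutes F1 instead. An uninformative or fully redundant second feature
#' therefore yields a non-significant deviation.
#'
#' @param ranked1,ranked2 [RankedList-class] objects (possibly on different
#'   universes).
#' @param geneSet the gene set (symbols); membership is recomputed on the
#'   shared universe.
#' @param nPerm permutations (default 1e4).
#' @param seed integer seed.
#' @param alpha significance level for the outcome call (default 0.05).
#' @return list: `outcome`, `pF2Adds`, `pF1Adds`, `curves` (list of
#'   WalkCurve: f1, f2, joint, condF2gF1, condF1gF2), `N`, `K`.
#' @export
bivariateGsea <- function(ranked1, ranked2, geneSet, nPerm = 1e4, seed = 1,
                          alpha = 0.05) {
  universe <- intersect(ranked1@genes, ranked2@genes)
  stopIfNot(length(universe) >= 2, "shared universe too small")
  r1 <- restrictRanking(ranked1, universe, geneSet)
  r2 <- restrictRanking(ranked2, universe, geneSet)
  N <- length(universe)
  K <- sum(r1@member)
  w1 <- observedWalk(r1)
  w2 <- observedWalk(r2)
  joint <- jointWalk(r1, r2)
  cond2g1 <- conditionalWalk(w1, method = "closed")
  cond1g2 <- conditionalWalk(w2, method = "closed")
  thetaF2 <- curveTheta(joint@y, cond2g1@y)
  thetaF1 <- curveTheta(joint@y, cond1g2@y)

  members <- r1@genes[r1@member]
  rk1 <- match(members, r1@genes)
  rk2 <- match(members, r2@genes)
  nullTheta <- withSeed(seed, {
    t2 <- numeric(nPerm); t1 <- numeric(nPerm)
    for (i in seq_len(nPerm)) {
      # a uniformly random ranking puts the K members at a random K-subset
      # of the ranks
      rkRand <- sample.int(N, K)
      yj2 <- cumsum(tabulate(pmin(rk1, rkRand), N)) # F2 randomized
      yj1 <- cumsum(tabulate(pmin(rkRand, rk2), N)) # F1 randomized
      t2[i] <- curveTheta(yj2, cond2g1@y)
      t1[i] <- curveTheta(yj1, cond1g2@y)
    }
    list(t2 = t2, t1 = t1)
  })
  pF2 <- permPvalue(sum(nullTheta$t2 >= thetaF2 - 1e-12), nPerm)
  pF1 <- permPvalue(sum(nullTheta$t1 >= thetaF1 - 1e-12), nPerm)
  list(outcome = classifyBivariate(pF2, pF1, alpha),
       pF2Adds = pF2, pF1Adds = pF1,
       curves = list(f1 = w1, f2 = w2, joint = joint,
                     condF2gF1 = cond2g1, condF1gF2 = cond1g2),
       N = N, K = K)
}

#' Export walk curves as a rank-indexed table
#'
#' @param curves named list of [WalkCurve-class] objects on one rank axis.
#' @param path optional TSV output path.
#' @return data.frame with column `rank` plus one column per curve.
#' @export
exportWalkCurves <- function(curves, path = NULL) {
  N <- curves[[1]]@N
  out <- data.frame(rank = seq_len(N))
  for (nm in names(curves)) out[[nm]] <- curves[[nm]]@y
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
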