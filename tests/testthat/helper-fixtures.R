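# shared fixtures and independent brute-force oracles

deriveSeedForTest <- tissueMutAssoc:::deriveSeed

# all permutations of 1..n as a matrix (n! rows)
allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

tinyFreq <- function(freq, cohort = 100L) {
  new("FrequencyMatrix", freq = freq,
      cohortSizes = setNames(rep(cohort, ncol(freq)), colnames(freq)))
}

namedMat <- function(values, genes, tissues) {
  matrix(values, length(genes), length(tissues),
         dimnames = list(genes, tissues))
}

# brute-force gap split: try every successive boundary of the sorted
# sequence and keep the largest gap (lowest index on ties)
bruteGapSplit <- function(freqs) {
  if (max(freqs) == min(freqs)) return(NULL)
  ord <- order(freqs, names(freqs))
  s <- freqs[ord]
  best <- -Inf; bestB <- NA
  for (b in seq_len(length(s) - 1)) {
    gap <- s[b + 1] - s[b]
    if (gap > best) { best <- gap; bestB <- b }
  }
  list(group1 = names(s)[seq_len(bestB)],
       group2 = names(s)[(bestB + 1):length(s)], gap = unname(best))
}

# one-sided KS distance computed from scratch with ecdf (right-continuous)
bruteKsD <- function(on, off, side = "greater") {
  xs <- sort(unique(c(on, off)))
  d <- ecdf(off)(xs) - ecdf(on)(xs)
  switch(side, greater = max(d), less = max(-d), two.sided = max(abs(d)))
}

# exact permutation distribution of the KS distance over all label
# assignments (independent of the package's enumeration)
bruteKsPermP <- function(values, labels, side = "greater") {
  n <- length(values); m <- sum(labels)
  Demp <- bruteKsD(values[labels], values[!labels], side)
  combos <- combn(n, m)
  ds <- apply(combos, 2, function(ix) {
    lab <- rep(FALSE, n); lab[ix] <- TRUE
    bruteKsD(values[lab], values[!lab], side)
  })
  mean(ds >= Demp - 1e-12)
}

# brute-force per-type top-k union
bruteTopK <- function(freq, k) {
  out <- character(0)
  for (j in seq_len(ncol(freq))) {
    v <- freq[, j]
    ord <- order(-v)
    kk <- min(k, length(v))
    thr <- v[ord][kk]
    out <- c(out, rownames(freq)[v >= thr])
  }
  sort(unique(out))
}

# generic hypergeometric pmf by subset enumeration: drawing `draw` items
# from a pool of `poolSize` with `poolMarked` marked, P(x marked)
enumHyper <- function(poolSize, poolMarked, draw, x) {
  marked <- seq_len(poolMarked)
  combos <- combn(poolSize, draw)
  mean(apply(combos, 2, function(ix) sum(ix %in% marked) == x))
}
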