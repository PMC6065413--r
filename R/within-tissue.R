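## Within-tissue two-group comparisons: split genes by chromatin state or
## expression threshold, compare value distributions with a one-sided KS
## statistic evaluated by label permutation.

#' Split genes into two groups within a tissue
#'
#' @param x named vector: "ON"/"OFF" states (rule "state"), or numeric
#'   values for threshold rules.
#' @param rule "state" (ON vs OFF), "fpkm" (x > cutoff vs rest) or
#'   "percentile" (x above the q-th percentile of the expressed universe).
#' @param cutoff FPKM cutoff (rule "fpkm", default 10).
#' @param q percentile in (0, 100) (rule "percentile").
#' @return logical vector, TRUE for the high/ON group, named by gene, or
#'   NULL (comparison skipped) when a group comes out empty.
#' @export
splitGenes <- function(x, rule = c("state", "fpkm", "percentile"),
                       cutoff = 10, q = 50) {
  rule <- match.arg(rule)
  lab <- switch(rule,
    state = x == "ON",
    fpkm = x > cutoff,
    percentile = x > quantile(x, q / 100, names = FALSE))
  if (all(lab) || !any(lab)) return(NULL) # skipped: one group empty
  lab
}

# one-sided asymptotic KS p-value for distance D with group sizes m, n
ksAsymptoticP <- function(D, m, n) {
  if (is.na(D)) return(NA_real_)
  min(1, exp(-2 * D^2 * m * n / (m + n)))
}

#' One-sided KS permutation test between two gene groups
#'
#' The test statistic is the one-sided KS p-value (default alternative: the
#' ON/high group is stochastically larger). Group labels are permuted
#' `nPerm` times and the permutation p-value is the pseudocount fraction of
#' permutations whose KS p is at or below the empirical one (equivalently,
#' whose KS distance is at least the empirical distance, since group sizes
#' are fixed).
#'
#' @param values named numeric vector, one value per gene.
#' @param labels logical vector (TRUE = ON/high group), same length.
#' @param side "greater" (ON group larger), "less", or "two.sided".
#' @param nPerm number of label permutations (default 1e5).
#' @param seed integer seed.
#' @param exact if TRUE, enumerate all distinct label assignments instead of
#'   sampling (feasible for small gene counts); the returned p is then the
#'   exact fraction of assignments at least as extreme.
#' @return list: `ksP` (the test statistic), `D`, `permP`, `nPerm`, group
#'   sizes, `side`, `flags`.
#' @export
ksPermutationTest <- function(values, labels, side = c("greater", "less",
                              "two.sided"), nPerm = 1e5, seed = 1,
                              exact = FALSE) {
  side <- match.arg(side)
  stopIfNot(length(values) == length(labels), "values/labels length mismatch")
  flags <- character(0)
  m <- sum(labels); n <- sum(!labels)
  if (m < 2 || n < 2) {
    return(list(ksP = NA_real_, D = NA_real_, permP = NA_real_,
                nPerm = 0L, nOn = m, nOff = n, side = side,
                flags = "group smaller than 2"))
  }
  sideCode <- match(side, c("greater", "less", "two.sided"))
  D <- cpp_ks_distance(values, labels, sideCode)
  ksP <- ksAsymptoticP(D, m, n)
  if (sd(values[labels]) == 0 && sd(values[!labels]) == 0 &&
      values[labels][1] == values[!labels][1]) {
    return(list(ksP = 1, D = 0, permP = 1, nPerm = 0L, nOn = m, nOff = n,
                side = side, flags = "constant values in both groups"))
  }
  if (exact) {
    total <- length(values)
    stopIfNot(choose(total, m) <= 2e4,
              "exact enumeration infeasible; use sampling")
    assigns <- combn(total, m)
    Ds <- apply(assigns, 2, function(ix) {
      lab <- rep(FALSE, total); lab[ix] <- TRUE
      cpp_ks_distance(values, lab, sideCode)
    })
    permP <- mean(Ds >= D - 1e-12)
    nPerm <- ncol(assigns)
  } else {
    nullD <- withSeed(seed,
      cpp_ks_perm_null(values, labels, as.integer(nPerm), sideCode))
    permP <- permPvalue(sum(nullD >= D - 1e-12), nPerm)
  }
  list(ksP = ksP, D = D, permP = permP, nPerm = as.integer(nPerm),
       nOn = m, nOff = n, side = side, flags = flags)
}

#' Subsampling robustness of the within-tissue comparison
#'
#' Re-runs [ksPermutationTest()] on uniform random gene subsamples at each
#' fold (a fold of f keeps 1/f of the genes).
#'
#' @param values,labels,side,nPerm as in [ksPermutationTest()].
#' @param folds integer vector of subsampling folds.
#' @param seed integer seed.
#' @return data.frame: fold, nGenes, nOn, nOff, D, ksP, permP, skipped.
#' @export
subsampleRobustness <- function(values, labels, folds = c(5, 10, 25, 50, 100),
                                nPerm = 1e5, seed = 1, side = "greater") {
  rows <- lapply(folds, function(f) {
    keep <- withSeed(deriveSeed(seed, "fold", f),
                     sample(length(values), max(1, floor(length(values) / f))))
    v <- values[keep]; l <- labels[keep]
    if (sum(l) < 2 || sum(!l) < 2)
      return(data.frame(fold = f, nGenes = length(keep), nOn = sum(l),
                        nOff = sum(!l), D = NA, ksP = NA, permP = NA,
                        skipped = TRUE))
    r <- ksPermutationTest(v, l, side = side, nPerm = nPerm,
                           seed = deriveSeed(seed, "test", f))
    data.frame(fold = f, nGenes = length(keep), nOn = r$nOn, nOff = r$nOff,
               D = r$D, ksP = r$ksP, permP = r$permP, skipped = FALSE)
  })
  do.call(rbind, rows)
}

#' Export two-group histogram data (bin edges and per-group counts)
#'
#' Produces the tabular data behind per-tissue distribution panels; bins
#' never feed the statistics.
#'
#' @param values named numeric vector.
#' @param labels logical group labels (TRUE = ON/high).
#' @param breaks number of bins or vector of bin edges.
#' @param path optional TSV output path.
#' @return data.frame: binStart, binEnd, countOn, countOff.
#' @export
exportGroupHistogram <- function(values, labels, breaks = 30, path = NULL) {
  edges <- if (length(breaks) == 1)
    seq(min(values), max(values), length.out = breaks + 1) else breaks
  hOn <- hist(values[labels], breaks = edges, plot = FALSE)
  hOff <- hist(values[!labels], breaks = edges, plot = FALSE)
  out <- data.frame(binStart = edges[-length(edges)], binEnd = edges[-1],
                    countOn = hOn$counts, countOff = hOff$counts)
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
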