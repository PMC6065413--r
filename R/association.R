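## Cross-tissue association: gap-split of tissues by mutation frequency,
## median feature-value difference, permutation p-value, direction, and the
## permutation false discovery rate.

#' Split tissues at the largest gap of sorted mutation frequencies
#'
#' Tissues are sorted ascending by mutation frequency; the boundary is the
#' successive pair with the largest gap (ties: the lowest boundary index).
#' Tissues at or below the low boundary point form the lowly mutated group
#' 1, the rest form the highly mutated group 2.
#'
#' @param freqs named numeric vector of per-tissue mutation frequencies.
#' @return list: `group1`, `group2` (tissue names), `gap`, `boundary`
#'   (index of the last group-1 tissue in the sorted order), `order`
#'   (sorted tissue names); or NULL ("no-split") when all frequencies are
#'   equal.
#' @export
gapSplit <- function(freqs) {
  stopIfNot(length(freqs) >= 2, "need at least 2 tissues")
  stopIfNot(!is.null(names(freqs)), "freqs must be named by tissue")
  if (max(freqs) == min(freqs)) return(NULL) # no-split: all equal
  ord <- order(freqs, names(freqs)) # value then name: deterministic ties
  sorted <- freqs[ord]
  gaps <- diff(sorted)
  b <- which.max(gaps) # first maximum = lowest boundary index
  list(group1 = names(sorted)[seq_len(b)],
       group2 = names(sorted)[(b + 1):length(sorted)],
       gap = unname(gaps[b]), boundary = b, order = names(sorted))
}

#' Median feature-value difference between tissue groups
#'
#' `median(values[group2]) - median(values[group1])`; tissues with missing
#' feature values are dropped (logged via attribute).
#'
#' @param values named numeric vector of per-tissue feature values.
#' @param split a [gapSplit()] result (or any list with `group1`/`group2`).
#' @return numeric statistic, or NA with attribute `flag` when a group has
#'   no remaining values.
#' @export
associationStatistic <- function(values, split) {
  g1 <- intersect(split$group1, names(values)[!is.na(values)])
  g2 <- intersect(split$group2, names(values)[!is.na(values)])
  if (!length(g1) || !length(g2)) {
    out <- NA_real_
    attr(out, "flag") <- "group emptied by missing feature values"
    return(out)
  }
  median(values[g2]) - median(values[g1])
}

#' Permutation association test for one gene
#'
#' For continuous features the tissues are split by [gapSplit()] on the
#' gene's mutation frequencies and the statistic is the median feature
#' difference (group 2 minus group 1). The null permutes mutation
#' frequencies over tissues; because the split depends only on the sorted
#' frequencies, this is realized as random assignment of tissues to the two
#' groups with the empirical group sizes fixed. For the chromatin feature
#' the grouping is the gene's EpiON/EpiOFF tissue states and the statistic
#' is the median mutation-frequency difference (ON minus OFF); the null
#' again permutes frequencies over tissues.
#'
#' The p-value is two-sided on |statistic| with the pseudocount form; the
#' direction is the sign of the statistic when p < alpha.
#'
#' @param featureValues named per-tissue feature values (continuous
#'   features) or "ON"/"OFF" states (chromatin).
#' @param freqs named per-tissue mutation frequencies.
#' @param type "continuous" or "chromatin".
#' @param nPerm permutations (default 1e5).
#' @param seed integer seed.
#' @param alpha significance level for direction calls (default 0.03).
#' @param labelPermutation for chromatin only: permute the chromatin state
#'   labels instead of the frequencies (alternative null; identical in
#'   distribution since both randomize the group assignment at fixed sizes).
#' @return list: `statistic`, `p`, `direction`, `split`, `nGroup1`,
#'   `nGroup2`, `nPerm`, `flags`.
#' @export
permutationAssociation <- function(featureValues, freqs,
                                   type = c("continuous", "chromatin"),
                                   nPerm = 1e5, seed = 1, alpha = 0.03,
                                   labelPermutation = FALSE) {
  type <- match.arg(type)
  flagged <- function(flag) list(statistic = NA_real_, p = NA_real_,
    direction = "none", split = NULL, nGroup1 = 0L, nGroup2 = 0L,
    nPerm = 0L, flags = flag)
  common <- intersect(names(freqs), names(featureValues))
  freqs <- freqs[common]
  featureValues <- featureValues[common]
  if (length(common) < 2) return(flagged("fewer than 2 tissues in common"))

  if (type == "chromatin") {
    split <- list(group1 = common[featureValues == "OFF"],
                  group2 = common[featureValues == "ON"])
    if (!length(split$group1) || !length(split$group2))
      return(flagged("constant chromatin states"))
    values <- freqs # statistic on mutation frequencies
  } else {
    split <- gapSplit(freqs)
    if (is.null(split)) return(flagged("no-split"))
    values <- featureValues
    if (anyNA(values)) {
      split$group1 <- intersect(split$group1, names(values)[!is.na(values)])
      split$group2 <- intersect(split$group2, names(values)[!is.na(values)])
      if (!length(split$group1) || !length(split$group2))
        return(flagged("group emptied by missing feature values"))
      values <- values[!is.na(values)]
    }
  }
  stat <- median(values[split$group2]) - median(values[split$group1])
  m <- length(split$group2)
  null <- withSeed(seed,
    cpp_perm_median_null(as.numeric(values[c(split$group2, split$group1)]),
                         as.integer(m), as.integer(nPerm)))
  p <- permPvalue(sum(abs(null) >= abs(stat) - 1e-12), nPerm)
  direction <- if (p < alpha && stat != 0) {
    if (stat > 0) "positive" else "negative"
  } else "none"
  list(statistic = stat, p = p, direction = direction, split = split,
       nGroup1 = length(split$group1), nGroup2 = m,
       nPerm = as.integer(nPerm), flags = character(0))
}

#' Association tests for every gene of one feature
#'
#' @param freq a [FrequencyMatrix-class] (columns are tissues/cancer types
#'   matched to the feature matrix columns).
#' @param featureMatrix genes x tissues matrix: numeric for continuous
#'   features, character "ON"/"OFF" for chromatin.
#' @param feature feature name recorded in the results.
#' @param type "continuous" or "chromatin".
#' @param nPerm,alpha,seed see [permutationAssociation()]; permutation
#'   streams are seeded per gene from `seed` so results do not depend on
#'   gene order.
#' @return data.frame: gene, feature, statistic, p, direction, nGroup1,
#'   nGroup2, flag.
#' @export
associateFeature <- function(freq, featureMatrix, feature = "feature",
                             type = c("continuous", "chromatin"),
                             nPerm = 1e5, alpha = 0.03, seed = 1) {
  type <- match.arg(type)
  f <- freqValues(freq)
  genes <- intersect(rownames(featureMatrix), rownames(f))
  rows <- lapply(genes, function(g) {
    fv <- featureMatrix[g, ]
    if (type == "continuous") fv <- as.numeric(featureMatrix[g, ])
    names(fv) <- colnames(featureMatrix)
    r <- permutationAssociation(fv, f[g, ], type = type, nPerm = nPerm,
                                seed = deriveSeed(seed, g, feature),
                                alpha = alpha)
    data.frame(gene = g, feature = feature, statistic = r$statistic,
               p = r$p, direction = r$direction, nGroup1 = r$nGroup1,
               nGroup2 = r$nGroup2,
               flag = if (length(r$flags)) r$flags[1] else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation false discovery rate for a feature
#'
#' Each gene's mutation-frequency labels are permuted `nLabelPerm` times and
#' the association test is re-run on the permuted data; the FDR estimate is
#' the total number of significant calls in the permuted data divided by
#' (number of significant empirical genes x nLabelPerm).
#'
#' Permuting a gene's frequencies leaves its sorted frequency values (hence
#' the gap-split group sizes and the permutation null) unchanged, so the
#' permuted-data statistic is an independent draw of the group assignment;
#' this is exploited to reuse one null sample per gene.
#'
#' @param freq a [FrequencyMatrix-class].
#' @param featureMatrix as in [associateFeature()].
#' @param results the empirical [associateFeature()] table for this feature.
#' @param type "continuous" or "chromatin".
#' @param nLabelPerm label permutations per gene (default 100).
#' @param nPerm permutations inside each re-test (default 1e5).
#' @param alpha significance level (default 0.03).
#' @param seed integer seed.
#' @return list: `fdr`, `nSignificantEmpirical`, `nSignificantPermuted`,
#'   `nLabelPerm`, `flag` ("undefined" when no empirical significant gene).
#' @export
estimateFdr <- function(freq, featureMatrix, results,
                        type = c("continuous", "chromatin"),
                        nLabelPerm = 100, nPerm = 1e5, alpha = 0.03,
                        seed = 1) {
  type <- match.arg(type)
  nSigEmp <- sum(results$p < alpha, na.rm = TRUE)
  if (nSigEmp == 0)
    return(list(fdr = NA_real_, nSignificantEmpirical = 0L,
                nSignificantPermuted = 0L, nLabelPerm = nLabelPerm,
                flag = "undefined: no empirical significant gene"))
  f <- freqValues(freq)
  genes <- intersect(rownames(featureMatrix), rownames(f))
  nSigPerm <- 0L
  for (g in genes) {
    fv <- if (type == "continuous") {
      v <- as.numeric(featureMatrix[g, ]); names(v) <- colnames(featureMatrix)
      v
    } else {
      v <- featureMatrix[g, ]; names(v) <- colnames(featureMatrix); v
    }
    common <- intersect(names(f[g, ]), names(fv))
    if (length(common) < 2) next
    freqs <- f[g, common]
    fvC <- fv[common]
    # group sizes under any frequency permutation
    if (type == "chromatin") {
      m <- sum(fvC == "ON"); n1 <- sum(fvC == "OFF")
      if (m == 0 || n1 == 0) next
      values <- freqs
    } else {
      split <- gapSplit(freqs)
      if (is.null(split)) next
      if (anyNA(fvC)) {
        ok <- names(fvC)[!is.na(fvC)]
        split$group1 <- intersect(split$group1, ok)
        split$group2 <- intersect(split$group2, ok)
        fvC <- fvC[ok]
      }
      m <- length(split$group2)
      if (m < 1 || !length(split$group1)) next
      values <- fvC
    }
    null <- withSeed(deriveSeed(seed, "fdrnull", g),
      cpp_perm_median_null(as.numeric(values), as.integer(m),
                           as.integer(nPerm)))
    sortedAbs <- sort(abs(null))
    # each label permutation draws a fresh statistic from the same null
    stats <- withSeed(deriveSeed(seed, "fdrstat", g),
      cpp_perm_median_null(as.numeric(values), as.integer(m),
                           as.integer(nLabelPerm)))
    nGE <- length(sortedAbs) -
      findInterval(abs(stats) - 1e-12, sortedAbs)
    ps <- permPvalue(nGE, nPerm)
    nSigPerm <- nSigPerm + sum(ps < alpha)
  }
  list(fdr = nSigPerm / (nSigEmp * nLabelPerm),
       nSignificantEmpirical = as.integer(nSigEmp),
       nSignificantPermuted = as.integer(nSigPerm),
       nLabelPerm = nLabelPerm, flag = "")
}

#' Summarize association results for one feature
#'
#' Counts and fractions of significant genes, the positive fraction among
#' significant genes, and an optional cross-tabulation of direction against
#' a user-supplied gene-class table (e.g. oncogene/tumor-suppressor labels).
#'
#' @param results an [associateFeature()] table.
#' @param alpha significance level (default 0.03).
#' @param fdr optional [estimateFdr()] result to carry into the summary.
#' @param geneClasses optional data.frame with columns `gene`, `class`.
#' @return one-row data.frame: feature, nTotal, nSignificant,
#'   fractionSignificant, positiveFraction (NA when no significant gene),
#'   estimatedFdr; with attribute `classTable` when `geneClasses` given.
#' @export
summarizeFeature <- function(results, alpha = 0.03, fdr = NULL,
                             geneClasses = NULL) {
  stopIfNot(nrow(results) > 0, "empty results")
  tested <- results[!is.na(results$p), , drop = FALSE]
  nTotal <- nrow(tested)
  sig <- tested[tested$p < alpha, , drop = FALSE]
  nSig <- nrow(sig)
  out <- data.frame(
    feature = results$feature[1],
    nTotal = nTotal,
    nSignificant = nSig,
    fractionSignificant = if (nTotal) nSig / nTotal else NA_real_,
    positiveFraction = if (nSig) mean(sig$statistic > 0) else NA_real_,
    estimatedFdr = if (is.null(fdr)) NA_real_ else fdr$fdr,
    alpha = alpha, stringsAsFactors = FALSE)
  if (!is.null(geneClasses)) {
    merged <- merge(sig, geneClasses, by = "gene")
    attr(out, "classTable") <- table(merged$class, merged$direction)
  }
  out
}
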