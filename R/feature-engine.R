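## Candidate normal-tissue features: chromatin accessibility, own expression,
## pathway-neighbor activity, PPI-partner activity, and the remote-neighbor
## control feature.

# The four 25-state labels treated as accessible for active transcription.
.epiOnStates <- c("Active Transcription", "Transcribed - 5' preferential",
                  "Strong transcription", "Transcribed - 3' preferential")

#' Binarize a 25-state chromatin label
#'
#' The four transcription-associated states map to "ON" (accessible for
#' active transcription); every other label, including unknown strings, maps
#' to "OFF".
#'
#' @param stateName character vector of state-name strings.
#' @return character vector of "ON"/"OFF".
#' @export
accessibilityLabel <- function(stateName) {
  # tolerate unicode right single quotes in the 5'/3' labels
  canon <- gsub("’", "'", stateName)
  canon <- gsub("–", "-", canon)
  ifelse(canon %in% .epiOnStates, "ON", "OFF")
}

#' Aggregate replicate accessibility calls by strict majority
#'
#' A gene is "ON" in a tissue only if strictly more than half of the
#' tissue's epigenome calls are "ON".
#'
#' @param states character vector of "ON"/"OFF" calls.
#' @return "ON" or "OFF".
#' @export
aggregateStates <- function(states) {
  stopIfNot(length(states) >= 1, "cannot aggregate an empty state list")
  if (sum(states == "ON") > length(states) / 2) "ON" else "OFF"
}

#' Per-gene accessibility category across tissues
#'
#' @param cst a [ChromatinStateTable-class].
#' @return named character vector: "EpiAllON", "EpiAllOFF" or "EpiDIFF".
#' @export
accessibilityCategory <- function(cst) {
  b <- binaryStates(cst)
  apply(b, 1, function(row) {
    if (all(row == "ON")) "EpiAllON"
    else if (all(row == "OFF")) "EpiAllOFF"
    else "EpiDIFF"
  })
}

#' Genes at exact shortest-path distance d
#'
#' @param net a [PpiNetwork-class].
#' @param gene gene symbol.
#' @param d shortest-path distance (>= 1); may be a vector of distances, in
#'   which case the union over them is returned.
#' @return character vector of gene symbols (excluding `gene` itself); empty
#'   with attribute `missing = TRUE` when the gene is absent from the network.
#' @export
nthDegreeNeighbors <- function(net, gene, d) {
  stopIfNot(all(d >= 1), "distance must be >= 1")
  g <- ppiGraph(net)
  if (!gene %in% igraph::V(g)$name) {
    out <- character(0)
    attr(out, "missing") <- TRUE
    return(out)
  }
  dist <- igraph::distances(g, v = gene)[1, ]
  sort(names(dist)[is.finite(dist) & dist %in% d & names(dist) != gene])
}

# Null distributions of mean expression for random gene sets, cached per
# (tissue, set size). Returns tissue -> size -> sorted null means.
nullMeanCache <- function(exprMat, sizes, nNull, seed) {
  sizes <- sort(unique(sizes))
  cache <- vector("list", ncol(exprMat))
  names(cache) <- colnames(exprMat)
  for (ts in colnames(exprMat)) {
    x <- exprMat[, ts]
    cache[[ts]] <- lapply(setNames(sizes, sizes), function(k) {
      withSeed(deriveSeed(seed, "null", ts, k),
               sort(cpp_null_means(x, as.integer(k), as.integer(nNull))))
    })
  }
  cache
}

# upper-tail pseudocount p from a sorted null vector
upperTailP <- function(obs, sortedNull) {
  n <- length(sortedNull)
  nGE <- n - findInterval(obs - 1e-12, sortedNull)
  permPvalue(nGE, n)
}

#' Activity score of a gene set in a tissue
#'
#' The score is the negative log of the upper-tail permutation p-value of
#' the observed mean expression against means of `nNull` uniformly drawn
#' gene sets of the same size (drawn without replacement from all genes with
#' expression in the tissue). A pseudocount keeps p in (0, 1] and the score
#' finite, bounded by log(nNull + 1).
#'
#' @param observedMean mean expression of the neighbor set in the tissue.
#' @param neighborCount set size (>= 1).
#' @param tissueExpr numeric vector of all genes' expression in the tissue.
#' @param nNull number of null draws (default 1e5).
#' @param seed integer seed.
#' @param exhaustive if TRUE, enumerate all size-`neighborCount` subsets
#'   instead of sampling (only for small universes; always exact for
#'   singleton sets).
#' @return list with elements `p`, `score`, `mean`, `size`, `nNull`.
#' @export
activityScore <- function(observedMean, neighborCount, tissueExpr,
                          nNull = 1e5, seed = 1, exhaustive = FALSE) {
  n <- length(tissueExpr)
  stopIfNot(neighborCount >= 1 && neighborCount <= n,
            "neighbor count exceeds the gene universe")
  if (exhaustive || neighborCount == 1) {
    nullMeans <- if (neighborCount == 1) tissueExpr else {
      stopIfNot(choose(n, neighborCount) <= 2e5,
                "exhaustive enumeration infeasible for this universe")
      combn(tissueExpr, neighborCount, mean)
    }
    p <- upperTailP(observedMean, sort(nullMeans))
    nEff <- length(nullMeans)
  } else {
    nullMeans <- withSeed(seed,
      cpp_null_means(tissueExpr, as.integer(neighborCount),
                     as.integer(nNull)))
    p <- upperTailP(observedMean, sort(nullMeans))
    nEff <- nNull
  }
  list(p = p, score = -log(p), mean = observedMean, size = neighborCount,
       nNull = nEff)
}

# neighbors of a gene in one pathway: union of in/out edge partners when
# directed edges exist for the pathway, else (behind membershipFallback) all
# other members.
pathwayNeighborSet <- function(gene, pw, pathways, membershipFallback) {
  e <- pathways@edges
  sub <- e[e$pathway == pw, , drop = FALSE]
  if (nrow(sub)) {
    nb <- unique(c(sub$dst[sub$src == gene], sub$src[sub$dst == gene]))
    return(setdiff(nb, gene))
  }
  if (!membershipFallback) return(character(0))
  setdiff(pathwayMembers(pathways)[[pw]], gene)
}

#' Gene x tissue feature matrices for the four candidate features and the
#' control feature
#'
#' @param genes candidate gene symbols.
#' @param expr an [ExpressionMatrix-class] (typically z-normalized).
#' @param chromatin optional [ChromatinStateTable-class].
#' @param pathways optional [PathwayCollection-class].
#' @param ppi optional [PpiNetwork-class].
#' @param nNull null draws per activity score (default 1e5).
#' @param seed master seed.
#' @param membershipFallback when a pathway has no directed edges, treat all
#'   other members as neighbors (default TRUE).
#' @param control include the remote-neighbor control feature.
#' @return named list of feature matrices (genes x tissues): `expression`,
#'   and where inputs allow `chromatin` (character "ON"/"OFF", EpiDIFF genes
#'   only), `pathway`, `ppi`, `control`. Genes excluded from a feature are
#'   absent from its rows; exclusion reasons are in attribute `excluded`.
#' @export
computeFeatures <- function(genes, expr, chromatin = NULL, pathways = NULL,
                            ppi = NULL, nNull = 1e5, seed = 1,
                            membershipFallback = TRUE, control = FALSE) {
  em <- exprValues(expr)
  genes <- intersect(genes, rownames(em))
  tissues <- colnames(em)
  out <- list()
  excluded <- list()

  # own expression: singleton activity score, exact null (full expression
  # vector), no sampling needed
  exprFeat <- vapply(tissues, function(ts) {
    x <- em[, ts]
    sorted <- sort(x)
    vapply(genes, function(g) -log(upperTailP(x[[g]], sorted)), 0)
  }, numeric(length(genes)))
  dimnames(exprFeat) <- list(genes, tissues)
  out$expression <- exprFeat

  if (!is.null(chromatin)) {
    b <- binaryStates(chromatin)
    common <- intersect(genes, rownames(b))
    cat3 <- accessibilityCategory(chromatin)[common]
    diffGenes <- common[cat3 == "EpiDIFF"]
    excluded$chromatin <- c(
      setNames(rep("no chromatin data", length(setdiff(genes, common))),
               setdiff(genes, common)),
      setNames(paste0("constant (", cat3[cat3 != "EpiDIFF"], ")"),
               common[cat3 != "EpiDIFF"]))
    out$chromatin <- b[diffGenes, intersect(tissues, colnames(b)),
                       drop = FALSE]
  }

  neighborFeature <- function(neighborsOf, tag) {
    nbs <- lapply(setNames(genes, genes), neighborsOf)
    nbs <- lapply(nbs, function(nb) intersect(nb, rownames(em)))
    keep <- vapply(nbs, length, 0L) >= 1L
    excluded[[tag]] <<- setNames(rep("no mapped neighbors", sum(!keep)),
                                 genes[!keep])
    if (!any(keep)) return(NULL)
    nbs <- nbs[keep]
    sizes <- vapply(nbs, length, 0L)
    cache <- nullMeanCache(em, sizes, nNull, deriveSeed(seed, tag))
    feat <- vapply(tissues, function(ts) {
      x <- em[, ts]
      vapply(nbs, function(nb)
        -log(upperTailP(mean(x[nb]), cache[[ts]][[as.character(length(nb))]])),
        0)
    }, numeric(length(nbs)))
    dimnames(feat) <- list(names(nbs), tissues)
    feat
  }

  if (!is.null(pathways)) {
    pwOf <- lapply(setNames(genes, genes), function(g)
      names(Filter(function(m) g %in% m, pathwayMembers(pathways))))
    # per-pathway scores, then the minimum p (= max score) over mapped pathways
    allSets <- list()
    for (g in genes) for (pw in pwOf[[g]]) {
      nb <- intersect(pathwayNeighborSet(g, pw, pathways, membershipFallback),
                      rownames(em))
      if (length(nb)) allSets[[paste0(g, "\r", pw)]] <- nb
    }
    if (length(allSets)) {
      sizes <- vapply(allSets, length, 0L)
      cache <- nullMeanCache(em, sizes, nNull, deriveSeed(seed, "pathway"))
      gOf <- sub("\r.*", "", names(allSets))
      keptGenes <- unique(gOf)
      feat <- vapply(tissues, function(ts) {
        x <- em[, ts]
        ps <- vapply(allSets, function(nb)
          upperTailP(mean(x[nb]), cache[[ts]][[as.character(length(nb))]]), 0)
        vapply(keptGenes, function(g) -log(min(ps[gOf == g])), 0)
      }, numeric(length(unique(gOf))))
      dimnames(feat) <- list(keptGenes, tissues)
      out$pathway <- feat
      excluded$pathway <- setNames(
        rep("no mapped pathway with expressed neighbors",
            length(setdiff(genes, keptGenes))), setdiff(genes, keptGenes))
    } else {
      excluded$pathway <- setNames(rep("no mapped pathway", length(genes)),
                                   genes)
    }
  }

  if (!is.null(ppi)) {
    g <- ppiGraph(ppi)
    out$ppi <- neighborFeature(function(gene) {
      if (!gene %in% igraph::V(g)$name) return(character(0))
      igraph::V(g)$name[as.integer(
        igraph::neighbors(g, gene))]
    }, "ppi")
  }

  if (control && !is.null(ppi)) {
    cf <- controlFeature(genes, ppi, expr, seed = deriveSeed(seed, "control"))
    out$control <- cf
    excluded$control <- attr(cf, "excluded")
  }

  attr(out, "excluded") <- excluded
  out
}

#' Remote-neighbor control feature
#'
#' For each gene, 5 genes are sampled without replacement from the pool of
#' its third- to seventh-degree PPI neighbors; the feature value in every
#' tissue is the mean expression of those same 5 genes. Genes whose pool has
#' fewer than 5 members are excluded.
#'
#' @param genes candidate gene symbols.
#' @param ppi a [PpiNetwork-class].
#' @param expr an [ExpressionMatrix-class].
#' @param seed integer seed (one realization; resample with a new seed for
#'   repeated control draws).
#' @return genes x tissues numeric matrix with attribute `excluded`.
#' @export
controlFeature <- function(genes, ppi, expr, seed = 1) {
  em <- exprValues(expr)
  g <- ppiGraph(ppi)
  present <- intersect(genes, igraph::V(g)$name)
  dmat <- igraph::distances(g, v = present)
  rows <- list()
  excluded <- setNames(rep("absent from PPI network",
                           length(setdiff(genes, present))),
                       setdiff(genes, present))
  for (gene in present) {
    d <- dmat[gene, ]
    pool <- intersect(names(d)[is.finite(d) & d >= 3 & d <= 7], rownames(em))
    if (length(pool) < 5) {
      excluded[gene] <- "fewer than 5 remote neighbors"
      next
    }
    picked <- withSeed(deriveSeed(seed, gene),
                       sample(pool, 5, replace = FALSE))
    rows[[gene]] <- colMeans(em[picked, , drop = FALSE])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, ncol(em), dimnames = list(NULL, colnames(em)))
  attr(out, "excluded") <- excluded
  out
}

#' Export a feature matrix as TSV with sidecar metadata
#'
#' Writes the gene x tissue matrix and a JSON sidecar (`<path>.meta.json`)
#' recording how the feature was computed (null draws, seed, pseudocount
#' rule) so a run can be audited.
#'
#' @param mat genes x tissues feature matrix.
#' @param path TSV output path.
#' @param nNull,seed the parameters used to compute the matrix.
#' @return invisibly, the sidecar path.
#' @export
exportFeatureMatrix <- function(mat, path, nNull = NA, seed = NA) {
  write.table(data.frame(gene = rownames(mat), mat, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(nNull = nNull, seed = seed,
               pseudocount = "p = (1 + s) / (1 + nNull)",
               nGenes = nrow(mat), tissues = colnames(mat))
  sidecar <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}

#' Single-gene convenience wrappers for the activity features
#'
#' `expressionActivity` scores the gene's own expression (singleton set,
#' exact null); `ppiActivity` its first-degree PPI partners; and
#' `pathwayActivity` its immediate pathway neighbors with the minimum
#' p-value over mapped pathways.
#'
#' @param gene gene symbol.
#' @param expr an [ExpressionMatrix-class].
#' @param tissue tissue name.
#' @param net a [PpiNetwork-class].
#' @param pathways a [PathwayCollection-class].
#' @param nNull,seed,membershipFallback see [activityScore()].
#' @return an activity-score list (see [activityScore()]); NULL when the
#'   gene is excluded from the feature (no mapped pathway / no partner).
#' @export
expressionActivity <- function(gene, expr, tissue, nNull = 1e5, seed = 1) {
  x <- exprValues(expr)[, tissue]
  activityScore(x[[gene]], 1, x, nNull = nNull, seed = seed)
}

#' @rdname expressionActivity
#' @export
ppiActivity <- function(gene, net, expr, tissue, nNull = 1e5, seed = 1) {
  nb <- nthDegreeNeighbors(net, gene, 1)
  nb <- intersect(nb, rownames(exprValues(expr)))
  if (!length(nb)) return(NULL)
  x <- exprValues(expr)[, tissue]
  activityScore(mean(x[nb]), length(nb), x, nNull = nNull, seed = seed)
}

#' @rdname expressionActivity
#' @export
pathwayActivity <- function(gene, pathways, expr, tissue, nNull = 1e5,
                            seed = 1, membershipFallback = TRUE) {
  pws <- names(Filter(function(m) gene %in% m, pathwayMembers(pathways)))
  if (!length(pws)) return(NULL)
  x <- exprValues(expr)[, tissue]
  best <- NULL
  for (pw in pws) {
    nb <- intersect(pathwayNeighborSet(gene, pw, pathways, membershipFallback),
                    rownames(exprValues(expr)))
    if (!length(nb)) next
    sc <- activityScore(mean(x[nb]), length(nb), x, nNull = nNull,
                        seed = deriveSeed(seed, gene, pw))
    if (is.null(best) || sc$p < best$p) best <- sc
  }
  best
}
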