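## Synthetic input bundles with planted ground truth: mutation-frequency
## profiles with a pronounced high/low gap in a minority of tissues, feature
## values shifted between the groups by a configurable effect size, planted
## chromatin categories, scale-free-ish networks, pathway memberships, and a
## planted cancer-gene set concentrated among pathway-associated genes.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the data regime the pipeline targets: a dozen tissue
#' types, cohorts of ~100 patients, low background mutation frequencies with
#' a prominent gap (0.3) in 1-3 high tissues for associated genes, and a
#' 3-SD feature shift between high and low groups.
#'
#' @param nGenes number of genes (default 400).
#' @param nTissues number of tissue/cancer types (default 12).
#' @param cohortSize patients per cancer type (default 100).
#' @param baseFreq background per-tissue mutation probability (default 0.02).
#' @param gap planted frequency elevation of high-group tissues (default
#'   0.3).
#' @param effectSize feature shift between high and low groups, in SD units
#'   of the expression noise (default 3).
#' @param fracExpression,fracChromatin,fracPathway,fracPpi fractions of
#'   genes planted as associated with each feature (disjoint blocks; must
#'   sum to <= 1 with room for carriers).
#' @param negativeShare fraction of planted genes with negative direction
#'   (default 0.25).
#' @param highTissueRange range of high-group sizes (default 1:3).
#' @param exprMean,exprSd mean and SD of the FPKM-like expression noise.
#' @param network "pa" (preferential attachment, default) or "er".
#' @param meanDegree mean PPI degree (default 4).
#' @param nPathwaysBackground random background pathways (default 20).
#' @param pathwaySizeRange member-count range for pathways (default 5:10).
#' @param carriersPerGene neighbor genes carrying the planted shift for each
#'   pathway-associated gene (default 5).
#' @param fracAllOn,fracAllOff,fracNullEpiDiff chromatin background mix for
#'   genes without a planted chromatin association.
#' @param cancerGeneProbAssoc,cancerGeneProbNull probability of planted
#'   cancer-gene membership for pathway-associated vs other genes (defaults
#'   0.6 / 0.05).
#' @param makeCatalog generate the patient-level mutation catalog (default
#'   TRUE; skip for large calibration runs).
#' @param seed master seed (default 1).
#' @return a validated config list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nGenes = 400, nTissues = 12, cohortSize = 100,
    baseFreq = 0.02, gap = 0.3, effectSize = 3,
    fracExpression = 0.08, fracChromatin = 0.08, fracPathway = 0.08,
    fracPpi = 0.08, negativeShare = 0.25, highTissueRange = 1:3,
    exprMean = 50, exprSd = 10, network = c("pa", "er"), meanDegree = 4,
    nPathwaysBackground = 20, pathwaySizeRange = 5:10, carriersPerGene = 5,
    fracAllOn = 0.4, fracAllOff = 0.2, fracNullEpiDiff = 0.3,
    cancerGeneProbAssoc = 0.6, cancerGeneProbNull = 0.05,
    makeCatalog = TRUE, seed = 1) {
  cfg <- as.list(environment())
  cfg$network <- match.arg(network)
  fr <- fracExpression + fracChromatin + fracPathway + fracPpi
  stopIfNot(fr <= 1, "planted fractions must sum to <= 1")
  stopIfNot(nGenes >= 10 && nTissues >= 2 && cohortSize >= 1,
            "counts must be positive (nGenes >= 10, nTissues >= 2)")
  nPath <- ceiling(fracPathway * nGenes)
  stopIfNot(fr * nGenes + nPath * carriersPerGene <= nGenes,
            "infeasible config: not enough genes for pathway carriers")
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Generate a complete synthetic input bundle
#'
#' See [syntheticConfig()] for the planted structure. All randomness derives
#' from the config's master seed; the same config yields an identical
#' bundle.
#'
#' @param config a [syntheticConfig()] list.
#' @return a [SyntheticBundle-class].
#' @export
generateBundle <- function(config = syntheticConfig()) {
  cfg <- config
  nG <- cfg$nGenes; nT <- cfg$nTissues
  genes <- sprintf("g%04d", seq_len(nG))
  tissues <- sprintf("T%02d", seq_len(nT))

  ## PPI network (built first: PPI-planted genes must have partners that can
  ## carry the shift)
  g <- withSeed(deriveSeed(cfg$seed, "net"), {
    if (cfg$network == "pa")
      igraph::sample_pa(nG, m = max(1, round(cfg$meanDegree / 2)),
                        directed = FALSE)
    else igraph::sample_gnp(nG, cfg$meanDegree / (nG - 1))
  })
  igraph::V(g)$name <- genes
  ppi <- PpiNetwork(g)

  ## planted roles: disjoint blocks along a shuffled gene order; PPI-planted
  ## genes are chosen greedily so each keeps >= 2 partners outside the
  ## planted focal set (otherwise the neighbor-borne shift is vacuous)
  ord <- withSeed(deriveSeed(cfg$seed, "roles"), sample(genes))
  nE <- round(cfg$fracExpression * nG); nC <- round(cfg$fracChromatin * nG)
  nP <- round(cfg$fracPathway * nG); nI <- round(cfg$fracPpi * nG)
  take <- function(n, used) if (n) ord[seq_len(n) + used] else character(0)
  used <- 0
  chromGenes <- take(nC, used); used <- used + nC
  exprGenes <- take(nE, used); used <- used + nE
  pathGenes <- take(nP, used); used <- used + nP
  rest <- ord[(used + 1):nG]
  focal <- c(chromGenes, exprGenes, pathGenes)
  ppiGenes <- character(0)
  adj <- igraph::adjacent_vertices(ppiGraph(ppi), genes)
  names(adj) <- genes
  for (cand in rest) {
    if (length(ppiGenes) >= nI) break
    nb <- igraph::V(ppiGraph(ppi))$name[as.integer(adj[[cand]])]
    if (length(setdiff(nb, c(focal, ppiGenes, cand))) >= 2)
      ppiGenes <- c(ppiGenes, cand)
  }
  stopIfNot(length(ppiGenes) == nI || nI == 0,
            "infeasible config: too few genes with >= 2 eligible partners")
  pool <- setdiff(rest, ppiGenes)
  planted <- c(chromGenes, exprGenes, pathGenes, ppiGenes)

  feature <- setNames(rep("null", nG), genes)
  feature[chromGenes] <- "chromatin"; feature[exprGenes] <- "expression"
  feature[pathGenes] <- "pathway"; feature[ppiGenes] <- "ppi"
  direction <- setNames(rep(0L, nG), genes)
  direction[planted] <- withSeed(deriveSeed(cfg$seed, "dirs"),
    ifelse(runif(length(planted)) < cfg$negativeShare, -1L, 1L))

  ## high-mutation tissue groups
  highTissues <- setNames(vector("list", nG), genes)
  highTissues[planted] <- withSeed(deriveSeed(cfg$seed, "high"),
    lapply(planted, function(g)
      sample(tissues, sample(cfg$highTissueRange, 1))))

  ## mutation frequencies: binomial draws over the cohort
  counts <- withSeed(deriveSeed(cfg$seed, "freq"), {
    m <- matrix(rbinom(nG * nT, cfg$cohortSize, cfg$baseFreq), nG, nT,
                dimnames = list(genes, tissues))
    for (g in planted) {
      ht <- highTissues[[g]]
      m[g, ht] <- rbinom(length(ht), cfg$cohortSize,
                         min(1, cfg$baseFreq + cfg$gap))
    }
    m
  })
  freq <- new("FrequencyMatrix", freq = counts / cfg$cohortSize,
              cohortSizes = setNames(rep(as.integer(cfg$cohortSize), nT),
                                     tissues))

  ## expression with planted shifts (shift magnitude = effectSize * exprSd)
  shift <- cfg$effectSize * cfg$exprSd
  exprM <- withSeed(deriveSeed(cfg$seed, "expr"),
    matrix(rnorm(nG * nT, cfg$exprMean, cfg$exprSd), nG, nT,
           dimnames = list(genes, tissues)))
  for (g in exprGenes)
    exprM[g, highTissues[[g]]] <- exprM[g, highTissues[[g]]] +
      direction[g] * shift

  # plant PPI signal on the focal genes' partners (only non-focal genes
  # receive shifts, so other planted signals stay clean)
  for (gene in ppiGenes) {
    nb <- setdiff(nthDegreeNeighbors(ppi, gene, 1), planted)
    if (length(nb))
      exprM[nb, highTissues[[gene]]] <- exprM[nb, highTissues[[gene]]] +
        direction[gene] * shift
  }

  ## pathways: one planted pathway per pathway-focal gene with dedicated
  ## carrier genes from the pool, plus random background pathways
  members <- list()
  carrierOf <- setNames(rep("", nG), genes)
  avail <- pool
  withSeed(deriveSeed(cfg$seed, "pathways"), {
    for (gene in pathGenes) {
      carriers <- sample(avail, cfg$carriersPerGene)
      avail <- setdiff(avail, carriers)
      members[[paste0("pw_", gene)]] <- c(gene, carriers)
      carrierOf[carriers] <- gene
      exprM[carriers, highTissues[[gene]]] <-
        exprM[carriers, highTissues[[gene]]] + direction[gene] * shift
    }
    for (i in seq_len(cfg$nPathwaysBackground)) {
      sz <- sample(cfg$pathwaySizeRange, 1)
      members[[sprintf("pw_bg%03d", i)]] <- sample(pool,
                                                   min(sz, length(pool)))
    }
  })
  pathways <- PathwayCollection(members)
  exprM <- pmax(exprM, 0)
  expression <- ExpressionMatrix(exprM)

  ## chromatin states: planted EpiDIFF aligned (or anti-aligned) with the
  ## high group; background mix of EpiAllON / EpiAllOFF / random EpiDIFF
  stateOn <- "Active Transcription"; stateOff <- "Quiescent"
  labels <- matrix(stateOn, nG, nT, dimnames = list(genes, tissues))
  withSeed(deriveSeed(cfg$seed, "chromatin"), {
    others <- setdiff(genes, chromGenes)
    nOth <- length(others)
    pDiff <- cfg$fracNullEpiDiff
    pRest <- max(0, 1 - cfg$fracAllOn - cfg$fracAllOff - pDiff)
    grp <- sample(c("allOn", "allOff", "diff", "rest"), nOth,
                  replace = TRUE,
                  prob = c(cfg$fracAllOn, cfg$fracAllOff, pDiff, pRest))
    for (i in seq_along(others)) {
      gn <- others[i]
      labels[gn, ] <- switch(grp[i],
        allOn = , rest = stateOn,
        allOff = stateOff,
        diff = ifelse(runif(nT) < 0.5, stateOn, stateOff))
    }
    for (gn in chromGenes) {
      ht <- highTissues[[gn]]
      onT <- if (direction[gn] > 0) ht else setdiff(tissues, ht)
      labels[gn, ] <- ifelse(tissues %in% onT, stateOn, stateOff)
    }
  })
  chromatin <- ChromatinStateTable(labels)

  ## planted cancer-gene set: concentrated among pathway-associated genes
  prob <- ifelse(feature == "pathway", cfg$cancerGeneProbAssoc,
                 cfg$cancerGeneProbNull)
  isCancer <- withSeed(deriveSeed(cfg$seed, "cancer"),
                       runif(nG) < prob)
  cancerGenes <- genes[isCancer]

  ## patient-level catalog reproducing the frequency counts
  catalog <- NULL
  if (cfg$makeCatalog) {
    cohorts <- lapply(setNames(tissues, tissues), function(ts)
      sprintf("%s_S%03d", ts, seq_len(cfg$cohortSize)))
    recs <- withSeed(deriveSeed(cfg$seed, "catalog"), {
      idx <- which(counts > 0, arr.ind = TRUE)
      do.call(rbind, lapply(seq_len(nrow(idx)), function(r) {
        gi <- idx[r, 1]; ti <- idx[r, 2]
        smp <- sample(cohorts[[tissues[ti]]], counts[gi, ti])
        data.frame(gene = genes[gi], sample = smp,
                   cancerType = tissues[ti],
                   variantClass = "Missense_Mutation",
                   stringsAsFactors = FALSE)
      }))
    })
    catalog <- MutationCatalog(recs, cohorts = cohorts, codingGenes = genes)
  }

  truth <- data.frame(gene = genes, feature = unname(feature),
                      direction = unname(direction),
                      effectSize = ifelse(feature == "null", 0,
                                          cfg$effectSize),
                      highTissues = vapply(highTissues, function(x)
                        paste(x, collapse = ","), ""),
                      carrierFor = unname(carrierOf),
                      cancerGene = unname(isCancer),
                      stringsAsFactors = FALSE)
  new("SyntheticBundle", catalog = catalog, freq = freq,
      expression = expression, chromatin = chromatin, pathways = pathways,
      ppi = ppi, cancerGenes = cancerGenes, truth = truth,
      config = unclass(cfg))
}

#' Evaluate pipeline results against planted ground truth
#'
#' @param results named list of [associateFeature()] tables (names are
#'   feature names matching the truth table's `feature` values).
#' @param truth the bundle's ground-truth table.
#' @param alpha significance level (default 0.03).
#' @param enrichmentP optional named numeric of univariate enrichment
#'   p-values per feature (carried into the report).
#' @return data.frame per feature: nPlantedTested, sensitivity, specificity,
#'   signRecovery, enrichmentP.
#' @export
truthEvaluation <- function(results, truth, alpha = 0.03,
                            enrichmentP = NULL) {
  rows <- lapply(names(results), function(feat) {
    res <- results[[feat]]
    res <- res[!is.na(res$p), , drop = FALSE]
    tr <- truth[match(res$gene, truth$gene), ]
    isPlanted <- tr$feature == feat
    detected <- res$p < alpha
    sens <- if (any(isPlanted)) mean(detected[isPlanted]) else NA_real_
    spec <- if (any(!isPlanted)) mean(!detected[!isPlanted]) else NA_real_
    tp <- isPlanted & detected
    signRec <- if (any(tp))
      mean(sign(res$statistic[tp]) == tr$direction[tp]) else NA_real_
    data.frame(feature = feat, nPlantedTested = sum(isPlanted),
               nNullTested = sum(!isPlanted), sensitivity = sens,
               specificity = spec, signRecovery = signRec,
               enrichmentP = if (is.null(enrichmentP)) NA_real_
                             else enrichmentP[[feat]] %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
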