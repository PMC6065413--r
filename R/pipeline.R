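## End-to-end orchestration: features -> associations -> FDR -> summaries ->
## univariate/bivariate enrichment, from a single config with reproducible
## seeds.

#' Build a pipeline run configuration
#'
#' @param nPerm association-test permutations (default 1e4; the
#'   paper-scale profile uses 1e5).
#' @param nPermEnrich enrichment permutations (default 1e4).
#' @param nNull activity-score null draws (default 1e4).
#' @param nLabelPerm label permutations per gene for the FDR (default 100).
#' @param alpha significance level (default 0.03).
#' @param topK per-type candidate count (default 50).
#' @param features features to run (subset of "chromatin", "expression",
#'   "pathway", "ppi", "control").
#' @param doFdr,doEnrichment,doBivariate stage toggles.
#' @param paperScale if TRUE, raise all permutation counts to 1e5.
#' @param seed master seed.
#' @param outputDir optional directory for TSV/JSON outputs.
#' @return config list of class `RunConfig`.
#' @export
runConfig <- function(nPerm = 1e4, nPermEnrich = 1e4, nNull = 1e4,
                      nLabelPerm = 100, alpha = 0.03, topK = 50,
                      features = c("chromatin", "expression", "pathway",
                                   "ppi"),
                      doFdr = TRUE, doEnrichment = TRUE, doBivariate = TRUE,
                      paperScale = FALSE, seed = 1, outputDir = NULL) {
  cfg <- as.list(environment())
  if (paperScale) cfg$nPerm <- cfg$nPermEnrich <- cfg$nNull <- 1e5
  stopIfNot(cfg$nPerm >= 100 && cfg$nPermEnrich >= 100 && cfg$nNull >= 100,
            "permutation counts must be >= 100")
  class(cfg) <- "RunConfig"
  cfg
}

#' Load a RunConfig from a YAML file
#' @param path YAML file whose keys match [runConfig()] arguments.
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(runConfig, vals)
}

#' Run the full association and enrichment pipeline
#'
#' Stages: candidate selection (union of per-type top-k most mutated),
#' expression z-normalization, feature computation, per-feature gap-split
#' permutation association, permutation FDR, Table-1-style summaries,
#' univariate enrichment random walks against the planted/supplied gene
#' set, and bivariate enrichment for every feature pair. Gene exclusion
#' counts are conserved per feature (input = tested + excluded).
#'
#' @param bundle a [SyntheticBundle-class], or a named list with elements
#'   `freq` (FrequencyMatrix), `expression` (ExpressionMatrix), and
#'   optionally `chromatin`, `pathways`, `ppi`, `geneSet`
#'   (see [readInputs()]).
#' @param config a [runConfig()] list.
#' @param geneSet optional gene set (overrides the bundle's cancer genes).
#' @return list: `candidates`, `features`, `associations` (per-feature
#'   tables), `fdr`, `summaries`, `rankings`, `enrichment` (univariate
#'   p-values and curves), `bivariate`, `accounting`, `manifest`. Written
#'   as TSV/JSON when `config$outputDir` is set.
#' @export
runPipeline <- function(bundle, config = runConfig(), geneSet = NULL) {
  cfg <- config
  if (is(bundle, "SyntheticBundle")) {
    inputs <- list(freq = bundle@freq, expression = bundle@expression,
                   chromatin = bundle@chromatin, pathways = bundle@pathways,
                   ppi = bundle@ppi, geneSet = bundle@cancerGenes)
  } else inputs <- bundle
  if (!is.null(geneSet)) inputs$geneSet <- geneSet
  stopIfNot(!is.null(inputs$freq), "pipeline stage inputs: freq is required")
  stopIfNot(!is.null(inputs$expression),
            "pipeline stage inputs: expression is required")

  candidates <- selectCandidates(inputs$freq, k = cfg$topK)
  exprZ <- if (inputs$expression@normalized) inputs$expression
           else zNormalize(inputs$expression)

  feats <- computeFeatures(candidates, exprZ,
    chromatin = if ("chromatin" %in% cfg$features) inputs$chromatin,
    pathways = if ("pathway" %in% cfg$features) inputs$pathways,
    ppi = if (any(c("ppi", "control") %in% cfg$features)) inputs$ppi,
    nNull = cfg$nNull, seed = deriveSeed(cfg$seed, "features"),
    control = "control" %in% cfg$features)

  useFeats <- intersect(cfg$features, names(feats))
  associations <- list(); fdr <- list(); summaries <- list()
  accounting <- list()
  for (feat in useFeats) {
    fm <- feats[[feat]]
    if (is.null(fm) || nrow(fm) == 0) next
    type <- if (feat == "chromatin") "chromatin" else "continuous"
    res <- associateFeature(inputs$freq, fm, feature = feat, type = type,
                            nPerm = cfg$nPerm, alpha = cfg$alpha,
                            seed = deriveSeed(cfg$seed, "assoc", feat))
    associations[[feat]] <- res
    excl <- attr(feats, "excluded")[[feat]]
    accounting[[feat]] <- list(nInput = length(candidates),
                               nTested = sum(res$flag == ""),
                               nExcluded = length(excl) +
                                 sum(res$flag != ""),
                               reasons = c(table(unname(excl)),
                                           table(res$flag[res$flag != ""])))
    f <- if (cfg$doFdr)
      estimateFdr(inputs$freq, fm, res, type = type,
                  nLabelPerm = cfg$nLabelPerm, nPerm = cfg$nPerm,
                  alpha = cfg$alpha,
                  seed = deriveSeed(cfg$seed, "fdr", feat))
    else NULL
    fdr[[feat]] <- f
    summaries[[feat]] <- summarizeFeature(res, alpha = cfg$alpha, fdr = f)
  }
  summaryTable <- do.call(rbind, summaries)

  rankings <- list(); enrichment <- NULL; bivariate <- NULL
  if (cfg$doEnrichment && length(inputs$geneSet)) {
    enrichP <- c(); curves <- list()
    for (feat in names(associations)) {
      res <- associations[[feat]]
      p <- setNames(res$p, res$gene)
      if (!any(names(p)[!is.na(p)] %in% inputs$geneSet)) next
      rk <- rankGenes(p, inputs$geneSet, feature = feat)
      rankings[[feat]] <- rk
      ow <- observedWalk(rk)
      ew <- expectedWalk(ow@N, ow@K)
      wp <- walkPvalue(ow, ew, nPerm = cfg$nPermEnrich,
                       seed = deriveSeed(cfg$seed, "enrich", feat))
      enrichP[feat] <- wp$p
      curves[[feat]] <- list(observed = ow, expected = ew)
    }
    enrichment <- list(p = enrichP, curves = curves)
    if (cfg$doBivariate && length(rankings) >= 2) {
      pairs <- combn(names(rankings), 2, simplify = FALSE)
      bivariate <- lapply(pairs, function(pr) {
        bg <- bivariateGsea(rankings[[pr[1]]], rankings[[pr[2]]],
                            inputs$geneSet, nPerm = cfg$nPermEnrich,
                            seed = deriveSeed(cfg$seed, "biv", pr[1], pr[2]),
                            alpha = 0.05)
        c(list(f1 = pr[1], f2 = pr[2]), bg[c("outcome", "pF2Adds",
                                             "pF1Adds", "N", "K")])
      })
    }
  }

  manifest <- list(package = "tissueMutAssoc",
                   version = as.character(utils::packageVersion(
                     "tissueMutAssoc")),
                   config = unclass(cfg), nCandidates = length(candidates),
                   features = useFeats, timestamp = format(Sys.time()))
  out <- list(candidates = candidates, features = feats,
              associations = associations, fdr = fdr,
              summaries = summaryTable, rankings = rankings,
              enrichment = enrichment, bivariate = bivariate,
              accounting = accounting, manifest = manifest)
  if (!is.null(cfg$outputDir)) writePipelineOutputs(out, cfg$outputDir)
  invisible(out)
}

# write per-feature association TSVs, summary, walk curves and the manifest
writePipelineOutputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (feat in names(out$associations))
    write.table(out$associations[[feat]],
                file.path(dir, paste0("association_", feat, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$summaries))
    write.table(out$summaries, file.path(dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(out$enrichment)) {
    for (feat in names(out$enrichment$curves)) {
      cl <- out$enrichment$curves[[feat]]
      exportWalkCurves(cl, file.path(dir, paste0("walk_", feat, ".tsv")))
    }
  }
  if (!is.null(out$bivariate)) {
    bt <- do.call(rbind, lapply(out$bivariate, function(b)
      data.frame(f1 = b$f1, f2 = b$f2, outcome = b$outcome,
                 pF2Adds = b$pF2Adds, pF1Adds = b$pF1Adds)))
    write.table(bt, file.path(dir, "bivariate.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}
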