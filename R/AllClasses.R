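#' @import methods
#' @importFrom stats median sd quantile dhyper ks.test setNames rbinom rnorm
#'   runif p.adjust
#' @importFrom utils read.delim write.table head combn
#' @importFrom graphics hist
#' @useDynLib tissueMutAssoc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' MutationCatalog: a somatic mutation call catalog
#'
#' Holds MAF-dialect somatic mutation records (gene symbol, sample barcode,
#' cancer type, variant classification) together with the declared cohort
#' (sample list) of every cancer type and the set of symbols flagged as
#' protein-coding. Duplicate records (same gene, sample, cancer type, variant
#' class and position key) are removed on construction.
#'
#' @slot records data.frame with columns `gene`, `sample`, `cancerType`,
#'   `variantClass` (and optionally `positionKey`).
#' @slot codingGenes character vector of symbols treated as protein-coding;
#'   genes not listed are treated as non-coding and all their records count
#'   towards mutation frequency.
#' @slot cohorts named list, cancer type -> character vector of sample IDs
#'   making up the cohort (the denominator of mutation frequency).
#' @export
setClass("MutationCatalog",
  slots = c(records = "data.frame", codingGenes = "character",
            cohorts = "list"))

setValidity("MutationCatalog", function(object) {
  req <- c("gene", "sample", "cancerType", "variantClass")
  miss <- setdiff(req, colnames(object@records))
  if (length(miss))
    return(paste("records is missing mandatory column(s):",
                 paste(miss, collapse = ", ")))
  if (is.null(names(object@cohorts)) || any(!nzchar(names(object@cohorts))))
    return("cohorts must be a named list (cancer type -> sample IDs)")
  bad <- setdiff(unique(object@records$cancerType), names(object@cohorts))
  if (length(bad))
    return(paste("records contain cancer type(s) absent from cohorts:",
                 paste(bad, collapse = ", ")))
  TRUE
})

#' FrequencyMatrix: gene x cancer-type mutation frequencies
#'
#' The mutational profile container: each row is a gene's vector of mutation
#' frequencies (fraction of cohort samples carrying at least one qualifying
#' mutation) across cancer types. Frequencies times cohort size are integral
#' patient counts by construction.
#'
#' @slot freq numeric matrix in \[0,1\], genes in rows, cancer types in columns.
#' @slot cohortSizes named integer vector, samples per cancer type.
#' @export
setClass("FrequencyMatrix",
  slots = c(freq = "matrix", cohortSizes = "integer"))

setValidity("FrequencyMatrix", function(object) {
  f <- object@freq
  if (is.null(rownames(f)) || is.null(colnames(f)))
    return("freq must have gene rownames and cancer-type colnames")
  if (any(f < 0 | f > 1)) return("frequencies must lie in [0, 1]")
  cs <- object@cohortSizes
  if (!identical(names(cs), colnames(f)))
    return("cohortSizes names must match freq colnames")
  if (any(cs <= 0L)) return("every cancer type needs a positive cohort size")
  counts <- sweep(f, 2, as.numeric(cs), `*`)
  if (max(abs(counts - round(counts))) > 1e-6)
    return("freq * cohortSize must be integral patient counts")
  TRUE
})

#' ExpressionMatrix: gene x tissue expression values
#'
#' Raw FPKM values are non-negative; after `zNormalize()` each gene row has
#' mean 0 and unit variance across tissues (constant rows are flagged and set
#' to zero).
#'
#' @slot values numeric matrix, genes in rows, tissues in columns.
#' @slot normalized logical scalar; TRUE after z-normalization.
#' @slot axis character, the normalization axis ("gene" or "tissue"); empty
#'   until normalized.
#' @slot constantGenes character, genes whose values were constant before
#'   normalization (their normalized rows are all zero).
#' @export
setClass("ExpressionMatrix",
  slots = c(values = "matrix", normalized = "logical", axis = "character",
            constantGenes = "character"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must have gene rownames and tissue colnames")
  if (!object@normalized && any(v < 0))
    return("raw FPKM values must be non-negative")
  if (object@normalized) {
    w <- if (identical(object@axis, "tissue")) t(v) else v
    keep <- setdiff(rownames(w), object@constantGenes)
    if (length(keep) && ncol(w) >= 2) {
      m <- rowMeans(w[keep, , drop = FALSE])
      if (max(abs(m)) > 1e-8)
        return("normalized vectors must have mean 0 (tolerance 1e-8)")
    }
  }
  TRUE
})

#' ChromatinStateTable: 25-state labels and derived binary accessibility
#'
#' Stores per-epigenome chromatin-state label strings and the derived binary
#' gene x tissue accessibility matrix ("ON"/"OFF"). When one tissue has
#' several epigenomes (e.g. brain regions) the binary calls are aggregated by
#' the strict-majority rule: a gene is ON in the tissue only if strictly more
#' than half of its epigenome calls are ON.
#'
#' @slot labels character matrix, genes x epigenomes, of state-name strings
#'   (may have zero columns when the table was supplied pre-binarized).
#' @slot tissueMap named character vector mapping epigenome column to tissue.
#' @slot binary character matrix, genes x tissues, values "ON"/"OFF".
#' @export
setClass("ChromatinStateTable",
  slots = c(labels = "matrix", tissueMap = "character", binary = "matrix"))

setValidity("ChromatinStateTable", function(object) {
  b <- object@binary
  if (is.null(rownames(b)) || is.null(colnames(b)))
    return("binary must have gene rownames and tissue colnames")
  if (!all(b %in% c("ON", "OFF")))
    return("binary entries must be 'ON' or 'OFF'")
  if (ncol(object@labels) > 0) {
    if (!identical(sort(unique(unname(object@tissueMap))), sort(colnames(b))))
      return("tissueMap tissues must match binary colnames")
    if (!all(names(object@tissueMap) %in% colnames(object@labels)))
      return("tissueMap names must be label colnames")
  }
  TRUE
})

#' PathwayCollection: pathway membership and optional directed edges
#'
#' @slot members named list, pathway id -> character vector of member genes.
#' @slot edges data.frame with columns `pathway`, `src`, `dst`; zero rows when
#'   only GMT membership is available.
#' @export
setClass("PathwayCollection",
  slots = c(members = "list", edges = "data.frame"))

setValidity("PathwayCollection", function(object) {
  if (length(object@members) && is.null(names(object@members)))
    return("members must be a named list")
  e <- object@edges
  if (nrow(e)) {
    if (!all(c("pathway", "src", "dst") %in% colnames(e)))
      return("edges needs columns pathway, src, dst")
    if (any(e$src == e$dst)) return("pathway edges may not be self-loops")
    for (pw in unique(e$pathway)) {
      gs <- object@members[[pw]]
      sub <- e[e$pathway == pw, ]
      if (!all(c(sub$src, sub$dst) %in% gs))
        return(paste0("edges of pathway ", pw, " reference non-members"))
    }
  }
  TRUE
})

#' PpiNetwork: undirected simple protein-protein interaction graph
#'
#' @slot graph an igraph object; undirected, no self-loops, no multi-edges.
#' @export
setClass("PpiNetwork", slots = c(graph = "ANY"))

setValidity("PpiNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::is_directed(g)) return("PPI graph must be undirected")
  if (any(igraph::which_loop(g))) return("PPI graph may not contain self-loops")
  if (any(igraph::which_multiple(g))) return("PPI graph must be simple")
  TRUE
})

#' RankedList: genes ordered by association p-value with set membership
#'
#' @slot genes character, genes in ascending order of association p-value
#'   (ties broken lexicographically by symbol).
#' @slot p numeric, the per-rank p-values (non-decreasing).
#' @slot member logical, gene-set membership flag per rank.
#' @slot feature character, name of the feature that produced the ranking.
#' @export
setClass("RankedList",
  slots = c(genes = "character", p = "numeric", member = "logical",
            feature = "character"))

setValidity("RankedList", function(object) {
  n <- length(object@genes)
  if (length(object@p) != n || length(object@member) != n)
    return("genes, p and member must have equal length")
  if (n && is.unsorted(object@p)) return("p must be non-decreasing along ranks")
  if (n && sum(object@member) < 1L)
    return("the gene set must intersect the universe (K >= 1)")
  if (anyDuplicated(object@genes)) return("duplicate genes in ranking")
  TRUE
})

#' WalkCurve: a rank-indexed cumulative gene-set count
#'
#' @slot x integer ranks 1..N.
#' @slot y numeric cumulative gene-set count at each rank (non-decreasing,
#'   y(0) = 0 implicitly); fractional for expected/conditional curves.
#' @slot kind one of "observed", "expected", "joint", "conditional".
#' @slot N integer, universe size.
#' @slot K integer, gene-set size within the universe.
#' @slot k numeric, the conditioning trace: member count among the top-n genes
#'   of the underlying (F1) list; equals y for observed curves, empty otherwise.
#' @export
setClass("WalkCurve",
  slots = c(x = "integer", y = "numeric", kind = "character", N = "integer",
            K = "integer", k = "numeric"))

setValidity("WalkCurve", function(object) {
  if (length(object@x) != length(object@y)) return("x and y lengths differ")
  if (length(object@y) && is.unsorted(object@y, strictly = FALSE))
    return("walk curves are non-decreasing")
  if (any(object@y < -1e-9)) return("y must be non-negative")
  if (!object@kind %in% c("observed", "expected", "joint", "conditional"))
    return("unknown curve kind")
  if (length(object@x) != object@N) return("curve must cover ranks 1..N")
  TRUE
})

#' SyntheticBundle: a generated input set with planted ground truth
#'
#' @slot catalog MutationCatalog or NULL (catalog generation can be skipped
#'   for large calibration runs).
#' @slot freq FrequencyMatrix.
#' @slot expression ExpressionMatrix (raw FPKM scale).
#' @slot chromatin ChromatinStateTable.
#' @slot pathways PathwayCollection.
#' @slot ppi PpiNetwork.
#' @slot cancerGenes character, the planted gene set.
#' @slot truth data.frame, one row per gene: planted feature, direction,
#'   effect size, high-group tissues, set membership.
#' @slot config list, the generating configuration (including the seed).
#' @export
setClass("SyntheticBundle",
  slots = c(catalog = "ANY", freq = "FrequencyMatrix",
            expression = "ExpressionMatrix", chromatin = "ChromatinStateTable",
            pathways = "PathwayCollection", ppi = "PpiNetwork",
            cancerGenes = "character", truth = "data.frame", config = "list"))

setValidity("SyntheticBundle", function(object) {
  if (!setequal(object@truth$gene, rownames(object@freq@freq)))
    return("ground truth must cover every gene in the frequency matrix")
  TRUE
})

## ---- accessors ----

#' @describeIn FrequencyMatrix-class the frequency matrix
#' @param object a FrequencyMatrix
#' @export
setGeneric("freqValues", function(object) standardGeneric("freqValues"))
#' @export
setMethod("freqValues", "FrequencyMatrix", function(object) object@freq)

#' @describeIn FrequencyMatrix-class cohort sizes per cancer type
#' @export
setGeneric("cohortSizes", function(object) standardGeneric("cohortSizes"))
#' @export
setMethod("cohortSizes", "FrequencyMatrix", function(object) object@cohortSizes)

#' @describeIn ExpressionMatrix-class the expression value matrix
#' @param object an ExpressionMatrix
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))
#' @export
setMethod("exprValues", "ExpressionMatrix", function(object) object@values)

#' @describeIn ChromatinStateTable-class the derived binary gene x tissue
#'   accessibility matrix ("ON"/"OFF")
#' @param object a ChromatinStateTable
#' @export
setGeneric("binaryStates", function(object) standardGeneric("binaryStates"))
#' @export
setMethod("binaryStates", "ChromatinStateTable", function(object) object@binary)

#' @describeIn PathwayCollection-class pathway membership list
#' @param object a PathwayCollection
#' @export
setGeneric("pathwayMembers", function(object) standardGeneric("pathwayMembers"))
#' @export
setMethod("pathwayMembers", "PathwayCollection", function(object) object@members)

#' @describeIn PpiNetwork-class the underlying igraph object
#' @param object a PpiNetwork
#' @export
setGeneric("ppiGraph", function(object) standardGeneric("ppiGraph"))
#' @export
setMethod("ppiGraph", "PpiNetwork", function(object) object@graph)

#' @describeIn WalkCurve-class curve heights y(x)
#' @param object a WalkCurve
#' @export
setGeneric("walkY", function(object) standardGeneric("walkY"))
#' @export
setMethod("walkY", "WalkCurve", function(object) object@y)

#' @describeIn SyntheticBundle-class the planted ground-truth table
#' @param object a SyntheticBundle
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @export
setMethod("groundTruth", "SyntheticBundle", function(object) object@truth)

## ---- show methods ----

setMethod("show", "MutationCatalog", function(object) {
  cat("MutationCatalog with", nrow(object@records), "records,",
      length(unique(object@records$gene)), "genes,",
      length(object@cohorts), "cancer types\n")
})

setMethod("show", "FrequencyMatrix", function(object) {
  cat("FrequencyMatrix:", nrow(object@freq), "genes x",
      ncol(object@freq), "cancer types; cohort sizes",
      paste(range(object@cohortSizes), collapse = "-"), "\n")
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix:", nrow(object@values), "genes x",
      ncol(object@values), "tissues;",
      if (object@normalized) paste0("z-normalized (axis=", object@axis, ")")
      else "raw FPKM", "\n")
})

setMethod("show", "ChromatinStateTable", function(object) {
  cat("ChromatinStateTable:", nrow(object@binary), "genes x",
      ncol(object@binary), "tissues (",
      ncol(object@labels), "source epigenomes )\n")
})

setMethod("show", "PathwayCollection", function(object) {
  cat("PathwayCollection:", length(object@members), "pathways,",
      nrow(object@edges), "directed edges\n")
})

setMethod("show", "PpiNetwork", function(object) {
  cat("PpiNetwork:", igraph::vcount(object@graph), "genes,",
      igraph::ecount(object@graph), "interactions\n")
})

setMethod("show", "RankedList", function(object) {
  cat("RankedList (", object@feature, "): N =", length(object@genes),
      ", K =", sum(object@member), "\n")
})

setMethod("show", "WalkCurve", function(object) {
  cat("WalkCurve [", object@kind, "]: N =", object@N, ", K =", object@K,
      ", terminal y =", if (length(object@y)) object@y[object@N] else 0, "\n")
})

setMethod("show", "SyntheticBundle", function(object) {
  cat("SyntheticBundle:", nrow(object@freq@freq), "genes x",
      ncol(object@freq@freq), "tissues;",
      sum(object@truth$feature != "null"), "planted associations;",
      length(object@cancerGenes), "planted cancer genes\n")
})
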