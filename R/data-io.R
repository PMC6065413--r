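#' Construct a MutationCatalog
#'
#' Builds a validated catalog from a record table, deduplicating identical
#' records (same gene, sample, cancer type, variant class and, when present,
#' position key).
#'
#' @param records data.frame with columns `gene`, `sample`, `cancerType`,
#'   `variantClass` and optionally `positionKey`.
#' @param cohorts named list mapping each cancer type to its cohort sample
#'   IDs. If missing, cohorts are inferred from the samples seen per cancer
#'   type (a lower bound on the true cohort).
#' @param codingGenes character vector of protein-coding symbols. Defaults to
#'   all genes in the catalog.
#' @return a [MutationCatalog-class] object.
#' @export
MutationCatalog <- function(records, cohorts = NULL, codingGenes = NULL) {
  stopIfNot(is.data.frame(records) && nrow(records) > 0,
            "records must be a non-empty data.frame")
  keyCols <- intersect(c("gene", "sample", "cancerType", "variantClass",
                         "positionKey"), colnames(records))
  records <- records[!duplicated(records[keyCols]), , drop = FALSE]
  rownames(records) <- NULL
  if (is.null(cohorts)) {
    cohorts <- split(records$sample, records$cancerType)
    cohorts <- lapply(cohorts, unique)
  }
  if (is.null(codingGenes)) codingGenes <- unique(records$gene)
  new("MutationCatalog", records = records, codingGenes = codingGenes,
      cohorts = cohorts)
}

#' Read a MAF-dialect mutation catalog from TSV
#'
#' Standard MAF column names (`Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Variant_Classification`) are remapped through `dialect`; a cancer-type
#' column is required (TCGA MAFs carry it as a project/cohort column, or it
#' can be supplied constant via `cancerType`).
#'
#' @param path TSV file path.
#' @param dialect named character vector mapping internal names (`gene`,
#'   `sample`, `variantClass`, `cancerType`, `positionKey`) to file columns.
#' @param cancerType optional constant cancer-type label when the file has no
#'   such column.
#' @param cohorts,codingGenes passed to [MutationCatalog()].
#' @return a [MutationCatalog-class]
#' @export
readMutationCatalog <- function(path,
    dialect = c(gene = "Hugo_Symbol", sample = "Tumor_Sample_Barcode",
                variantClass = "Variant_Classification",
                cancerType = "Cancer_Type"),
    cancerType = NULL, cohorts = NULL, codingGenes = NULL) {
  stopIfNot(file.exists(path), paste("no such file:", path))
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
  stopIfNot(nrow(tab) > 0, "empty mutation table")
  need <- c("gene", "sample", "variantClass")
  if (is.null(cancerType)) need <- c(need, "cancerType")
  for (field in need) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% colnames(tab))
      stop("missing mandatory column for '", field, "': ",
           if (is.null(col)) "<unmapped>" else col, call. = FALSE)
  }
  rec <- data.frame(gene = tab[[dialect[["gene"]]]],
                    sample = tab[[dialect[["sample"]]]],
                    variantClass = tab[[dialect[["variantClass"]]]],
                    stringsAsFactors = FALSE)
  rec$cancerType <- if (is.null(cancerType)) tab[[dialect[["cancerType"]]]]
                    else cancerType
  pk <- dialect["positionKey"]
  if (!is.na(pk) && pk %in% colnames(tab)) rec$positionKey <- tab[[pk]]
  MutationCatalog(rec, cohorts = cohorts, codingGenes = codingGenes)
}

#' The nonsynonymous variant classes counted for protein-coding genes
#'
#' Standard MAF non-silent convention; configurable in
#' [mutationFrequency()].
#' @export
nonsynonymousClasses <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site")
}

#' Mutation-frequency profiles from a catalog
#'
#' For each gene and cancer type, the fraction of cohort samples harboring at
#' least one qualifying mutation. For protein-coding genes only records whose
#' variant class is in `nonsynonymous` qualify; for non-coding genes every
#' record qualifies. A sample counts at most once per gene per cancer type.
#' Genes absent from a cohort's records get frequency 0.
#'
#' @param catalog a [MutationCatalog-class].
#' @param genes optional gene universe for the rows (default: all catalog
#'   genes).
#' @param nonsynonymous variant classes counted for coding genes.
#' @return a [FrequencyMatrix-class]
#' @export
mutationFrequency <- function(catalog, genes = NULL,
                              nonsynonymous = nonsynonymousClasses()) {
  rec <- catalog@records
  types <- names(catalog@cohorts)
  sizes <- vapply(catalog@cohorts, length, 0L)
  stopIfNot(all(sizes > 0), "cancer type with 0 cohort samples")
  if (is.null(genes)) genes <- sort(unique(rec$gene))
  coding <- rec$gene %in% catalog@codingGenes
  keep <- !coding | rec$variantClass %in% nonsynonymous
  rec <- rec[keep & rec$gene %in% genes, , drop = FALSE]
  freq <- matrix(0, length(genes), length(types),
                 dimnames = list(genes, types))
  if (nrow(rec)) {
    rec <- rec[!duplicated(rec[c("gene", "sample", "cancerType")]), ,
               drop = FALSE]
    cnt <- table(factor(rec$gene, levels = genes),
                 factor(rec$cancerType, levels = types))
    freq <- sweep(unclass(cnt), 2, as.numeric(sizes), `/`)
    dimnames(freq) <- list(genes, types)
  }
  new("FrequencyMatrix", freq = freq,
      cohortSizes = setNames(as.integer(sizes), types))
}

#' Candidate genes: union of per-type top-k most mutated
#'
#' Takes, for every cancer type, the `k` genes with the highest mutation
#' frequency (all genes tied at the k-th frequency are included, so the
#' result is order-independent) and returns the union.
#'
#' @param freq a [FrequencyMatrix-class].
#' @param k per-type count (default 50).
#' @return character vector of candidate gene symbols (sorted).
#' @export
selectCandidates <- function(freq, k = 50) {
  stopIfNot(k >= 1, "k must be >= 1")
  f <- freqValues(freq)
  picked <- lapply(colnames(f), function(ct) {
    v <- sort(f[, ct], decreasing = TRUE)
    if (k >= length(v)) return(rownames(f))
    names(v)[v >= v[k]]
  })
  sort(unique(unlist(picked)))
}

#' Construct an ExpressionMatrix from raw FPKM values
#'
#' @param values non-negative numeric matrix, genes x tissues, with dimnames.
#' @return an [ExpressionMatrix-class] (unnormalized).
#' @export
ExpressionMatrix <- function(values) {
  new("ExpressionMatrix", values = values, normalized = FALSE,
      axis = character(0), constantGenes = character(0))
}

#' Read an expression TSV (genes in rows, tissues in columns)
#' @param path TSV path with a header row and gene symbols in the first
#'   column.
#' @return an [ExpressionMatrix-class]
#' @export
readExpression <- function(path) {
  stopIfNot(file.exists(path), paste("no such file:", path))
  tab <- read.delim(path, check.names = FALSE)
  stopIfNot(nrow(tab) > 0 && ncol(tab) >= 2, "empty expression matrix")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  ExpressionMatrix(m)
}

#' Z-normalize expression values
#'
#' Per-gene z-scores across tissues (the default), or per-tissue across
#' genes. Constant vectors are flagged and set to zero.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param axis "gene" (normalize each gene across tissues) or "tissue".
#' @return a normalized [ExpressionMatrix-class]
#' @export
zNormalize <- function(expr, axis = c("gene", "tissue")) {
  axis <- match.arg(axis)
  v <- exprValues(expr)
  stopIfNot(ncol(v) >= 2, "z-normalization needs at least 2 tissues")
  if (axis == "tissue") v <- t(v)
  mu <- rowMeans(v)
  s <- apply(v, 1, sd)
  constant <- s == 0 | !is.finite(s)
  z <- (v - mu) / ifelse(constant, 1, s)
  z[constant, ] <- 0
  if (axis == "tissue") z <- t(z)
  new("ExpressionMatrix", values = z, normalized = TRUE, axis = axis,
      constantGenes = rownames(if (axis == "tissue") t(z) else z)[constant])
}

#' Read a chromatin-state table
#'
#' Accepts either a gene x epigenome table of 25-state label strings (which
#' is binarized via [accessibilityLabel()] and aggregated per tissue with the
#' strict-majority rule) or a gene x tissue table already holding "ON"/"OFF".
#'
#' @param path TSV path, gene symbols in the first column.
#' @param tissueMap named character vector, epigenome column -> tissue. If
#'   NULL each column is its own tissue.
#' @return a [ChromatinStateTable-class]
#' @export
readChromatinStates <- function(path, tissueMap = NULL) {
  stopIfNot(file.exists(path), paste("no such file:", path))
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopIfNot(nrow(tab) > 0 && ncol(tab) >= 2, "empty chromatin table")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  ChromatinStateTable(m, tissueMap = tissueMap)
}

#' Construct a ChromatinStateTable from a label or binary matrix
#'
#' @param labels character matrix, genes x epigenomes (25-state names) or
#'   genes x tissues ("ON"/"OFF").
#' @param tissueMap named character vector, epigenome -> tissue (NULL: one
#'   epigenome per tissue, column names reused).
#' @return a [ChromatinStateTable-class]
#' @export
ChromatinStateTable <- function(labels, tissueMap = NULL) {
  preBinary <- all(labels %in% c("ON", "OFF"))
  if (is.null(tissueMap))
    tissueMap <- setNames(colnames(labels), colnames(labels))
  if (preBinary && identical(unname(tissueMap), colnames(labels))) {
    return(new("ChromatinStateTable",
               labels = matrix(character(0), nrow(labels), 0,
                               dimnames = list(rownames(labels), NULL)),
               tissueMap = setNames(colnames(labels), colnames(labels)),
               binary = labels))
  }
  calls <- if (preBinary) labels else
    matrix(accessibilityLabel(labels), nrow(labels), ncol(labels),
           dimnames = dimnames(labels))
  tissues <- unique(unname(tissueMap))
  binary <- vapply(tissues, function(ts) {
    cols <- names(tissueMap)[tissueMap == ts]
    apply(calls[, cols, drop = FALSE], 1, aggregateStates)
  }, character(nrow(labels)))
  dimnames(binary) <- list(rownames(labels), tissues)
  new("ChromatinStateTable", labels = labels, tissueMap = tissueMap,
      binary = binary)
}

#' Read a pathway collection
#'
#' @param gmt optional GMT path (pathway id, description, members...). Lines
#'   with fewer than 3 fields are rejected with a warning.
#' @param edges optional TSV path with columns `pathway_id`, `src_gene`,
#'   `dst_gene` for directed pathway edges.
#' @return a [PathwayCollection-class]
#' @export
readPathways <- function(gmt = NULL, edges = NULL) {
  members <- list()
  if (!is.null(gmt)) {
    stopIfNot(file.exists(gmt), paste("no such file:", gmt))
    lines <- readLines(gmt)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3) {
        warning("rejecting GMT line with <3 fields: ",
                substr(ln, 1, 40), call. = FALSE)
        next
      }
      members[[parts[1]]] <- unique(parts[-(1:2)])
    }
  }
  edgeTab <- data.frame(pathway = character(0), src = character(0),
                        dst = character(0))
  if (!is.null(edges)) {
    stopIfNot(file.exists(edges), paste("no such file:", edges))
    tab <- read.delim(edges, stringsAsFactors = FALSE)
    stopIfNot(all(c("pathway_id", "src_gene", "dst_gene") %in% colnames(tab)),
              "edge table needs columns pathway_id, src_gene, dst_gene")
    edgeTab <- data.frame(pathway = tab$pathway_id, src = tab$src_gene,
                          dst = tab$dst_gene, stringsAsFactors = FALSE)
    for (pw in unique(edgeTab$pathway)) {
      sub <- edgeTab[edgeTab$pathway == pw, ]
      members[[pw]] <- unique(c(members[[pw]], sub$src, sub$dst))
    }
  }
  new("PathwayCollection", members = members, edges = edgeTab)
}

#' Construct a PathwayCollection in memory
#' @param members named list pathway -> member genes.
#' @param edges data.frame with columns pathway, src, dst (optional).
#' @return a [PathwayCollection-class]
#' @export
PathwayCollection <- function(members, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(pathway = character(0), src = character(0),
                        dst = character(0))
  new("PathwayCollection", members = members, edges = edges)
}

#' Read an undirected PPI edge list (2-column TSV)
#'
#' Symmetric duplicates ("A B" and "B A") collapse to one edge; self-loops
#' are dropped.
#'
#' @param path TSV path, two columns of gene symbols (header optional,
#'   detected by column count).
#' @param header logical, whether the file has a header row.
#' @return a [PpiNetwork-class]
#' @export
readPpi <- function(path, header = TRUE) {
  stopIfNot(file.exists(path), paste("no such file:", path))
  tab <- read.delim(path, header = header, stringsAsFactors = FALSE)
  stopIfNot(ncol(tab) >= 2 && nrow(tab) > 0, "empty PPI edge list")
  PpiNetwork(data.frame(a = as.character(tab[[1]]),
                        b = as.character(tab[[2]])))
}

#' Construct a PpiNetwork from an edge data.frame or igraph
#' @param x two-column data.frame of gene symbols, or an igraph object.
#' @return a [PpiNetwork-class]
#' @export
PpiNetwork <- function(x) {
  g <- if (igraph::is_igraph(x)) x else
    igraph::graph_from_data_frame(x, directed = FALSE)
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  new("PpiNetwork", graph = g)
}

#' Read a gene list (one symbol per line)
#' @param path file path.
#' @return character vector of unique symbols.
#' @export
readGeneList <- function(path) {
  stopIfNot(file.exists(path), paste("no such file:", path))
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Read and validate a full input set
#'
#' Thin orchestration over the individual readers; any component may be NULL
#' to skip it.
#'
#' @param paths named list with elements `mutations`, `expression`,
#'   `chromatin`, `gmt`, `pathwayEdges`, `ppi`, `geneSet` (any subset).
#' @param dialect passed to [readMutationCatalog()].
#' @param tissueMap passed to [readChromatinStates()].
#' @return named list of typed objects.
#' @export
readInputs <- function(paths, dialect = NULL, tissueMap = NULL) {
  out <- list()
  if (!is.null(paths$mutations)) {
    out$catalog <- if (is.null(dialect)) readMutationCatalog(paths$mutations)
                   else readMutationCatalog(paths$mutations, dialect = dialect)
  }
  if (!is.null(paths$expression))
    out$expression <- readExpression(paths$expression)
  if (!is.null(paths$chromatin))
    out$chromatin <- readChromatinStates(paths$chromatin, tissueMap)
  if (!is.null(paths$gmt) || !is.null(paths$pathwayEdges))
    out$pathways <- readPathways(gmt = paths$gmt, edges = paths$pathwayEdges)
  if (!is.null(paths$ppi)) out$ppi <- readPpi(paths$ppi)
  if (!is.null(paths$geneSet)) out$geneSet <- readGeneList(paths$geneSet)
  out
}
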