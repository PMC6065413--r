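test_that("mutation catalog parsing, dedup and validation work", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification\tCancer_Type",
               "TP53\tS1\tMissense_Mutation\tBRCA",
               "TP53\tS2\tSilent\tBRCA",
               "KRAS\tS1\tNonsense_Mutation\tLUAD"), tsv)
  cat <- readMutationCatalog(tsv)
  expect_s4_class(cat, "MutationCatalog")
  expect_equal(nrow(cat@records), 3)

  # duplicate records collapse
  rec <- data.frame(gene = c("A", "A"), sample = c("S1", "S1"),
                    cancerType = c("X", "X"),
                    variantClass = c("Missense_Mutation", "Missense_Mutation"))
  expect_equal(nrow(MutationCatalog(rec)@records), 1)

  # missing mandatory column is a hard error naming the column
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("Hugo_Symbol\tVariant_Classification", "TP53\tSilent"), bad)
  expect_error(readMutationCatalog(bad), "Tumor_Sample_Barcode")
})

test_that("GMT and PPI parsing follow format rules", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("pw1\tdesc\tA\tB", "short\tonly2fields"), gmt)
  expect_warning(pc <- readPathways(gmt = gmt), "<3 fields")
  expect_equal(pathwayMembers(pc), list(pw1 = c("A", "B")))

  ppiF <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "A\tB", "B\tA", "A\tA"), ppiF)
  net <- readPpi(ppiF)
  expect_equal(igraph::ecount(ppiGraph(net)), 1) # symmetric dedup, no loops
})

test_that("mutation frequency obeys the nonsynonymous and once-per-sample rules", {
  rec <- data.frame(
    gene = c("CODG", "CODG", "CODG", "CODG", "SILG", "MIR1"),
    sample = c("S1", "S1", "S2", "S2", "S1", "S3"),
    cancerType = "CT1",
    variantClass = c("Missense_Mutation", "Nonsense_Mutation",
                     "Missense_Mutation", "Missense_Mutation", "Silent",
                     "RNA"),
    positionKey = as.character(1:6))
  cohorts <- list(CT1 = c("S1", "S2", "S3", "S4"))
  cat <- MutationCatalog(rec, cohorts = cohorts,
                         codingGenes = c("CODG", "SILG"))
  fm <- mutationFrequency(cat)
  f <- freqValues(fm)
  expect_equal(f["CODG", "CT1"], 0.5)  # 2 of 4 samples, counted once each
  expect_equal(f["SILG", "CT1"], 0)    # only Silent records
  expect_equal(f["MIR1", "CT1"], 0.25) # non-coding: all records count

  # invariance under record order and duplication
  rec2 <- rbind(rec[sample(nrow(rec)), ], rec)
  cat2 <- MutationCatalog(rec2, cohorts = cohorts,
                          codingGenes = c("CODG", "SILG"))
  expect_equal(freqValues(mutationFrequency(cat2)), f)

  # zero-size cohort errors
  cat3 <- MutationCatalog(rec, cohorts = list(CT1 = character(0)))
  expect_error(mutationFrequency(cat3), "0 cohort")
})

test_that("candidate selection matches brute force and handles ties", {
  # disjoint top-2 sets
  f <- namedMat(c(.9, .8, 0, 0, 0, 0, .7, .6), paste0("g", 1:4),
                c("A", "B"))
  expect_equal(selectCandidates(tinyFreq(f * 100 / 100), k = 2),
               sort(paste0("g", 1:4)))
  # saturation
  expect_equal(selectCandidates(tinyFreq(f), k = 10), sort(paste0("g", 1:4)))
  # brute-force equivalence on random instances (incl. heavy ties)
  set.seed(7)
  for (i in 1:20) {
    nr <- sample(5:20, 1); nc <- sample(2:5, 1); k <- sample(1:4, 1)
    m <- namedMat(sample(0:5, nr * nc, replace = TRUE) / 100,
                  sprintf("g%02d", 1:nr), sprintf("t%d", 1:nc))
    expect_equal(selectCandidates(tinyFreq(m), k = k), bruteTopK(m, k))
  }
})

test_that("z-normalization yields unit-variance rows and flags constants", {
  m <- namedMat(c(1, 5, 0, 2, 5, 0, 3, 5, 0), paste0("g", 1:3),
                paste0("t", 1:3))
  em <- ExpressionMatrix(m)
  z <- zNormalize(em)
  v <- exprValues(z)
  expect_equal(unname(rowMeans(v)), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(unname(sd(v["g1", ])), 1, tolerance = 1e-10)
  expect_true(all(v["g2", ] == 0))
  expect_true("g2" %in% z@constantGenes)
  expect_true(all(v["g3", ] == 0))
  expect_error(zNormalize(ExpressionMatrix(m[, 1, drop = FALSE])),
               "at least 2")
})

test_that("matrix TSV round-trips reproduce values exactly", {
  m <- namedMat(round(runif(12), 6) * 1e6 / 1e6, paste0("g", 1:4),
                paste0("t", 1:3))
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(m), m, check.names = FALSE), f,
              sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readExpression(f)
  expect_identical(unname(exprValues(back)), unname(m))
})
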