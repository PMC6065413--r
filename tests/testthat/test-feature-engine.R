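test_that("25-state labels binarize to the four transcription states", {
  expect_equal(accessibilityLabel("Active Transcription"), "ON")
  expect_equal(accessibilityLabel("Strong transcription"), "ON")
  expect_equal(accessibilityLabel("Transcribed - 5' preferential"), "ON")
  expect_equal(accessibilityLabel("Transcribed - 3' preferential"), "ON")
  expect_equal(accessibilityLabel("Quiescent"), "OFF")
  expect_equal(accessibilityLabel("SomeUnknownState"), "OFF")
})

test_that("strict-majority aggregation and replicate idempotence hold", {
  expect_equal(aggregateStates(c("ON", "ON", "OFF")), "ON")
  expect_equal(aggregateStates(c("ON", "OFF")), "OFF") # 1/2 not > half
  expect_equal(aggregateStates("OFF"), "OFF")
  expect_error(aggregateStates(character(0)), "empty")
  # duplicating every replicate never changes the call
  set.seed(3)
  for (i in 1:50) {
    s <- sample(c("ON", "OFF"), sample(1:7, 1), replace = TRUE)
    expect_equal(aggregateStates(c(s, s)), aggregateStates(s))
  }
})

test_that("accessibility categories split AllON/AllOFF/DIFF", {
  b <- namedMat(c("ON", "OFF", "ON", "ON", "OFF", "OFF"),
                paste0("g", 1:3), c("t1", "t2"))
  cst <- ChromatinStateTable(b)
  expect_equal(unname(accessibilityCategory(cst)),
               c("EpiAllON", "EpiAllOFF", "EpiDIFF"))
})

test_that("nth-degree neighbors are exact shortest-path sets", {
  path <- PpiNetwork(data.frame(a = c("a", "b"), b = c("b", "c")))
  expect_equal(nthDegreeNeighbors(path, "b", 1), c("a", "c"))
  expect_equal(nthDegreeNeighbors(path, "a", 2), "c")
  tri <- PpiNetwork(data.frame(a = c("a", "b", "c"), b = c("b", "c", "a")))
  expect_equal(length(nthDegreeNeighbors(tri, "a", 2)), 0)
  missing <- nthDegreeNeighbors(path, "zz", 1)
  expect_equal(length(missing), 0)
  expect_true(attr(missing, "missing"))
})

test_that("activity score has the pseudocount tail and exact singleton null", {
  x <- setNames(1:100 / 10, sprintf("g%03d", 1:100))
  top <- activityScore(max(x) + 1, 3, x, nNull = 1000, seed = 1)
  expect_equal(top$p, 1 / 1001)
  expect_equal(top$score, log(1001))
  # singleton: p is the exact upper-tail rank
  med <- activityScore(median(x), 1, x, nNull = 1000, seed = 1)
  expect_equal(med$p, (1 + sum(x >= median(x))) / 101)
  expect_error(activityScore(1, 200, x), "exceeds")
})

test_that("sampled activity null converges to exhaustive enumeration", {
  set.seed(5)
  x <- setNames(rnorm(9), paste0("g", 1:9))
  obs <- mean(x[c(2, 5)])
  exact <- activityScore(obs, 2, x, exhaustive = TRUE)
  sampled <- activityScore(obs, 2, x, nNull = 20000, seed = 8)
  se <- sqrt(exact$p * (1 - exact$p) / 20000)
  # pseudocount offsets differ by O(1/#combos) between the two nulls
  expect_lt(abs(sampled$p - exact$p), 3 * se + 1 / (1 + choose(9, 2)))
})

test_that("activity p-values are uniform for random target genes", {
  set.seed(11)
  x <- setNames(rnorm(2000), sprintf("g%04d", 1:2000))
  draws <- sample(names(x), 2000, replace = TRUE)
  ps <- vapply(draws, function(g) activityScore(x[[g]], 1, x)$p, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("pathway activity takes the minimum p over mapped pathways", {
  genes <- sprintf("g%02d", 1:20)
  expr <- ExpressionMatrix(namedMat(abs(rnorm(40, 50, 10)), genes,
                                    c("t1", "t2")))
  pc <- PathwayCollection(list(pwA = c("g01", "g02", "g03"),
                               pwB = c("g01", "g10", "g11", "g12")))
  sc <- pathwayActivity("g01", pc, expr, "t1", nNull = 500, seed = 4)
  x <- exprValues(expr)[, "t1"]
  pA <- activityScore(mean(x[c("g02", "g03")]), 2, x, nNull = 500,
                      seed = deriveSeedForTest(4, "g01", "pwA"))
  pB <- activityScore(mean(x[c("g10", "g11", "g12")]), 3, x, nNull = 500,
                      seed = deriveSeedForTest(4, "g01", "pwB"))
  expect_equal(sc$p, min(pA$p, pB$p))
  # unmapped gene is excluded (NULL)
  expect_null(pathwayActivity("g20", pc, expr, "t1"))
})

test_that("ppi activity with one partner equals the partner's expression rank", {
  genes <- sprintf("g%02d", 1:12)
  expr <- ExpressionMatrix(namedMat(abs(rnorm(24, 50, 10)), genes,
                                    c("t1", "t2")))
  net <- PpiNetwork(data.frame(a = "g01", b = "g02"))
  a <- ppiActivity("g01", net, expr, "t1")
  b <- expressionActivity("g02", expr, "t1")
  expect_equal(a$p, b$p) # singleton sets use the exact null
  expect_null(ppiActivity("g07", net, expr, "t1")) # no partner
})

test_that("control feature pools distances 3-7 and is deterministic", {
  # chain a-b-c-d-e-f-g-h-i: from a, distances 3..7 are d..h (5 genes)
  chain <- data.frame(a = letters[1:8], b = letters[2:9])
  net <- PpiNetwork(chain)
  genes <- letters[1:9]
  expr <- ExpressionMatrix(namedMat(seq_len(18), genes, c("t1", "t2")))
  cf <- controlFeature("a", net, expr, seed = 3)
  expect_equal(unname(cf["a", "t1"]), mean(exprValues(expr)[4:8, "t1"]))
  # star center has no distance-3 neighbors -> excluded
  star <- PpiNetwork(data.frame(a = "hub", b = paste0("leaf", 1:6)))
  expr2 <- ExpressionMatrix(namedMat(seq_len(14), c("hub", paste0("leaf", 1:6)),
                                     c("t1", "t2")))
  cf2 <- controlFeature("hub", star, expr2, seed = 1)
  expect_equal(nrow(cf2), 0)
  expect_match(attr(cf2, "excluded")[["hub"]], "fewer than 5")
  # determinism
  expect_identical(controlFeature("a", net, expr, seed = 3), cf)
})
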