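test_that("chemical similarity follows the Tanimoto bit formula", {
  expect_identical(chemicalSimilarity(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_identical(chemicalSimilarity(c(1, 0, 1, 1, 0), c(0, 1, 1, 1, 0)),
                   0.5)
  expect_identical(chemicalSimilarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  # degenerate conventions: 0/0 resolved as identity
  expect_identical(chemicalSimilarity(c(0, 0), c(0, 0)), 1)
  expect_identical(chemicalSimilarity(c(0, 0), c(1, 0)), 0)
  expect_error(chemicalSimilarity(c(1, 0), c(1, 0, 1)), "mismatch")
})

test_that("Smith-Waterman raw scores match the affine-gap DP oracle", {
  p50 <- alignmentParams("BLOSUM50")
  raw <- gcmm:::swRawScore("HEAGAWGHEE", "PAWHEAE", p50)
  expect_equal(raw, oracleSmithWaterman("HEAGAWGHEE", "PAWHEAE",
                                        blosum("BLOSUM50"), 10, 1))
  norm <- smithWatermanSimilarity("HEAGAWGHEE", "PAWHEAE", p50)
  o11 <- oracleSmithWaterman("HEAGAWGHEE", "HEAGAWGHEE",
                             blosum("BLOSUM50"), 10, 1)
  o22 <- oracleSmithWaterman("PAWHEAE", "PAWHEAE", blosum("BLOSUM50"),
                             10, 1)
  expect_equal(norm, raw / sqrt(o11 * o22), tolerance = 1e-12)

  p62 <- alignmentParams()
  withr::with_seed(21, {
    for (i in 1:25) {
      s1 <- randomPeptide(sample(3:20, 1))
      s2 <- randomPeptide(sample(3:20, 1))
      expect_equal(gcmm:::swRawScore(s1, s2, p62),
                   oracleSmithWaterman(s1, s2, blosum("BLOSUM62"), 10, 1),
                   tolerance = 1e-10)
    }
  })
})

test_that("normalized alignment similarity is reflexive and degenerate-safe", {
  p <- alignmentParams()
  expect_identical(smithWatermanSimilarity("HEAGAWGHEE", "HEAGAWGHEE", p), 1)
  # no positively scoring residue pair: best local alignment is empty
  sub <- matrix(-1, 2, 2, dimnames = list(c("A", "W"), c("A", "W")))
  diag(sub) <- c(4, 4)
  pneg <- alignmentParams(substitutionMatrix = sub, gapOpening = 10,
                          gapExtension = 1)
  expect_identical(smithWatermanSimilarity("AAAA", "WWWW", pneg), 0)
  expect_error(smithWatermanSimilarity("", "AW", p), "non-empty")
  expect_error(smithWatermanSimilarity("A3A", "AW", p), "illegal")
})

test_that("therapeutic similarity averages cross pairs under e1 != e2", {
  p <- alignmentParams()
  seqs <- withr::with_seed(9, c(t1 = randomPeptide(25),
                                t2 = randomPeptide(25),
                                t3 = randomPeptide(25)))
  # a single shared target leaves no admissible pair
  expect_identical(therapeuticSimilarity("t1", "t1", seqs, p), 0)
  expect_identical(therapeuticSimilarity(character(), "t1", seqs, p), 0)
  s12 <- smithWatermanSimilarity(seqs["t1"], seqs["t2"], p)
  expect_equal(therapeuticSimilarity("t1", "t2", seqs, p), s12)
  s13 <- smithWatermanSimilarity(seqs["t1"], seqs["t3"], p)
  s23 <- smithWatermanSimilarity(seqs["t2"], seqs["t3"], p)
  expect_equal(therapeuticSimilarity(c("t1", "t2"), "t3", seqs, p),
               mean(c(s13, s23)))
  # shared token is skipped, not aligned against itself
  expect_equal(therapeuticSimilarity(c("t1", "t2"), c("t2", "t3"), seqs, p),
               mean(c(s12, s13, s23)))
  expect_error(therapeuticSimilarity("t9", "t1", seqs, p), "t9")
})

test_that("semantic values follow the max-over-children recursion", {
  dag <- DiseaseDAG(data.frame(parent = c("r", "a"), child = c("a", "s")))
  sv <- semanticValue(dag, "s")
  expect_identical(unname(sv$F[c("s", "a", "r")]), c(1, 1, 1))
  expect_identical(sv$DV, 3)
  dag1 <- DiseaseDAG(NULL, nodes = "x")
  expect_identical(semanticValue(dag1, "x")$DV, 1)
  svd <- semanticValue(dag, "s", delta = 0.5)
  expect_identical(unname(svd$F[c("s", "a", "r")]), c(1, 0.5, 0.25))
  expect_identical(svd$DV, 1.75)
  expect_error(semanticValue(dag, "zzz"), "not found")
})

test_that("semantic similarity matches shared-ancestry fractions", {
  # N(si) = {si,a,b,r}, N(sj) = {sj,b,r}: shared {b,r} -> 4/7 at delta 1
  dag <- DiseaseDAG(data.frame(
    parent = c("r", "r", "a", "b", "b"),
    child = c("a", "b", "si", "si", "sj")))
  expect_equal(semanticSimilarity(dag, "si", "sj"), 4 / 7)
  expect_identical(semanticSimilarity(dag, "si", "si"), 1)
  dag2 <- DiseaseDAG(data.frame(parent = c("r1", "r2"),
                                child = c("x", "y")))
  expect_identical(semanticSimilarity(dag2, "x", "y"), 0)
})

test_that("delta = 1 semantic similarity equals the closed form on random DAGs", {
  withr::with_seed(33, {
    for (rep in 1:50) {
      dag <- randomDag(sample(5:15, 1))
      pair <- sample(nodeIds(dag), 2)
      ni <- ancestorClosure(dag, pair[1])
      nj <- ancestorClosure(dag, pair[2])
      expect_equal(semanticSimilarity(dag, pair[1], pair[2]),
                   2 * length(intersect(ni, nj)) /
                     (length(ni) + length(nj)))
    }
  })
})

test_that("target Jaccard handles overlap and empty-set conventions", {
  expect_identical(targetJaccard(c("a", "b"), c("a", "b")), 1)
  expect_identical(targetJaccard(c("t1", "t2"), c("t2", "t3")), 1 / 3)
  expect_identical(targetJaccard("t1", character()), 0)
  expect_identical(targetJaccard(character(), character()), 1)
})

test_that("similarity matrices are symmetric, bounded and correctly tagged", {
  fp <- rbind(c(1, 0, 1, 1, 0), c(1, 0, 1, 1, 0), c(1, 0, 1, 1, 0))
  reg <- DrugRegistry(c("a", "b", "c"), fp)
  m <- buildSimilarityMatrix(reg, "chemical")
  expect_true(all(matrixValues(m) == 1))

  reg2 <- DrugRegistry(c("a", "b"), rbind(c(1, 0, 1, 1, 0),
                                          c(0, 1, 1, 1, 0)))
  m2 <- buildSimilarityMatrix(reg2, "chemical")
  expect_identical(matrixValues(m2)[1, 2], 0.5)
  expect_identical(viewTag(m2), "C")

  net <- tinyNet()
  for (v in c("C", "T", "M", "A")) {
    sm <- similarityView(net, v)
    vals <- matrixValues(sm)
    expect_identical(vals, t(vals))
    expect_true(min(vals) >= 0 && max(vals) <= 1)
  }
  # therapeutic self-similarity obeys the exclusion rule, not forced to 1
  gt <- matrixValues(similarityView(net, "T"))
  expect_identical(unname(gt["d1", "d1"]), 0)  # single target
})
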