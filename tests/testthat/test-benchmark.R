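test_that("cosine similarity has its geometric anchors", {
  v <- rnorm(10)
  expect_equal(cosineSimilarity(v, v), 1, tolerance = 1e-12)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSimilarity(c(1, 0), c(-1, 0)), -1)
  expect_equal(cosineSimilarity(c(2, 0), c(5, 0)), 1)   # scale invariance
  expect_error(cosineSimilarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosineSimilarity(1:3, 1:4), "dimension mismatch")
})

test_that("bootstrap null draws are reproducible, distinct-concept, bounded", {
  fix <- gaussianEmbedding(60, 8, 2, seed = 31)
  s1 <- bootstrapNull(fix$emb, fix$types, "CAT_1", "CAT_2", n = 5000, seed = 4)
  s2 <- bootstrapNull(fix$emb, fix$types, "CAT_1", "CAT_2", n = 5000, seed = 4)
  expect_identical(s1, s2)
  expect_length(s1, 5000L)
  expect_true(all(s1 >= -1 - 1e-12 & s1 <= 1 + 1e-12))
  s3 <- bootstrapNull(fix$emb, fix$types, "CAT_1", "CAT_2", n = 5000, seed = 5)
  expect_false(identical(s1, s3))
})

test_that("identical embeddings make every null draw cosine one", {
  V <- matrix(rep(c(1, 2, 3), each = 5), 5, 3,
              dimnames = list(sprintf("C%07d", 1:5), NULL))
  emb <- conceptEmbedding(V)
  types <- setNames(rep("CAT_1", 5), rownames(V))
  s <- bootstrapNull(emb, types, "CAT_1", "CAT_1", n = 1000, seed = 1)
  expect_true(all(abs(s - 1) < 1e-12))
  # a category with fewer than two embedded members is degenerate
  lone <- setNames(c("CAT_1", rep("CAT_2", 4)), rownames(V))
  expect_error(bootstrapNull(emb, lone, "CAT_1", "CAT_1", 100, 1),
               "degenerate null")
})

test_that("duplicated-vector pairs are discovered with high power", {
  set.seed(77)
  n <- 60L; d <- 50L
  V <- matrix(rnorm(n * d), n, d,
              dimnames = list(sprintf("C%07d", 1:n), NULL))
  # 10 related pairs: the second member duplicates the first
  rel <- data.frame(cui1 = rownames(V)[seq(1, 19, 2)],
                    cui2 = rownames(V)[seq(2, 20, 2)])
  V[rel$cui2, ] <- V[rel$cui1, ]
  emb <- conceptEmbedding(V)
  types <- setNames(rep("CAT_1", n), rownames(V))
  res <- relationshipPower(emb, rel, types, n = 2000, seed = 8)
  expect_gte(res$value, 0.9)
  expect_identical(res$nEvaluable, 10L)
})

test_that("null relationship pairs are discovered at about the level", {
  fix <- gaussianEmbedding(500, 50, 4, seed = 123)
  rel <- randomMatchedPairs(fix$types, 1000, seed = 42)
  res <- relationshipPower(fix$emb, rel, fix$types, n = 10000, seed = 5)
  expect_gte(res$value, 0.035)
  expect_lte(res$value, 0.065)
})

test_that("power is monotone in the planted mixing weight", {
  # shift the second member of each related pair toward the first by
  # mixing weight lambda; power must grow with lambda
  mkPower <- function(lambda) {
    set.seed(99)
    n <- 200L; d <- 50L
    V <- matrix(rnorm(n * d), n, d,
                dimnames = list(sprintf("C%07d", 1:n), NULL))
    i1 <- seq(1, 79, 2); i2 <- seq(2, 80, 2)
    V[i2, ] <- lambda * V[i1, ] + (1 - lambda) * V[i2, ]
    emb <- conceptEmbedding(V)
    types <- setNames(rep_len(paste0("CAT_", 1:2), n), rownames(V))
    rel <- data.frame(cui1 = rownames(V)[i1], cui2 = rownames(V)[i2])
    relationshipPower(emb, rel, types, n = 4000, seed = 12)$value
  }
  p0 <- mkPower(0); p4 <- mkPower(0.4); p8 <- mkPower(0.8)
  expect_gte(p8, p4)
  expect_gte(p4, p0)
  expect_true(p0 >= 0 && p8 <= 1)
})

test_that("missing embeddings are excluded and reported", {
  fix <- gaussianEmbedding(40, 6, 2, seed = 3)
  rel <- data.frame(cui1 = c(rownames(embeddingVectors(fix$emb))[1], "C9999999"),
                    cui2 = c(rownames(embeddingVectors(fix$emb))[2], "C9999998"))
  res <- relationshipPower(fix$emb, rel, fix$types, n = 500, seed = 2)
  expect_identical(res$nEvaluable, 1L)
  expect_identical(res$nTotal, 2L)
  expect_error(relationshipPower(fix$emb, rel[0, ], fix$types, 100, seed = 1),
               "empty benchmark")
})

test_that("marginal null mode supports the same-type benchmark", {
  fix <- gaussianEmbedding(120, 20, 3, seed = 14)
  rel <- randomMatchedPairs(fix$types, 200, seed = 6)
  res <- relationshipPower(fix$emb, rel, fix$types, n = 4000, seed = 7,
                           nullMode = "marginal")
  expect_true(res$value >= 0 && res$value <= 1)
  expect_identical(res$nEvaluable, 200L)
})

test_that("human similarity correlation is a rank correlation", {
  set.seed(55)
  fix <- gaussianEmbedding(30, 10, 2, seed = 20)
  U <- embeddingVectors(fix$emb)
  U <- U / sqrt(rowSums(U^2))
  ids <- rownames(U)
  pairs <- t(combn(ids[1:12], 2))
  cosv <- rowSums(U[pairs[, 1], ] * U[pairs[, 2], ])
  # any strictly increasing transform of the cosines gives rho = 1
  hs <- data.frame(cui1 = pairs[, 1], cui2 = pairs[, 2],
                   score = exp(3 * cosv) + 1)
  expect_equal(humanSimilarityCorrelation(fix$emb, hs)$value, 1)
  hs$score <- -hs$score
  expect_equal(humanSimilarityCorrelation(fix$emb, hs)$value, -1)
  hs$score <- 2
  expect_error(humanSimilarityCorrelation(fix$emb, hs), "degenerate ranking")
  expect_error(humanSimilarityCorrelation(fix$emb, hs[1:2, ]),
               "insufficient data")
})
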