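test_that("PMI matches the worked three-window example", {
  cm <- textCooccurrence(list(c("A", "B"), c("A", "B"), c("A", "C")),
                         vocab = c("A", "B", "C"))
  pmi <- pmiMatrix(cm, alpha = 1)
  # joint 2/3 over margins (1/2)(1/3)
  expect_equal(pmi["A", "B"], log(4), tolerance = 1e-12)
  expect_equal(pmi["A", "C"], log((1 / 3) / ((1 / 2) * (1 / 6))),
               tolerance = 1e-12)
})

test_that("PMI agrees with the dense brute-force oracle", {
  for (trial in 1:25) {
    counts <- rsymCounts(sample(5:20, 1), density = runif(1, 0.15, 0.6),
                         seed = trial)
    cm <- CoocMatrix(counts)
    for (alpha in c(1, 0.75, 0.5)) {
      got <- as.matrix(pmiMatrix(cm, alpha = alpha))
      want <- densePMIOracle(counts, alpha)
      nz <- counts > 0
      expect_lt(max(abs(got[nz] - want[nz])), 1e-10)
      expect_true(all(got[!nz] == 0))             # PMI only on nonzero cells
    }
  }
})

test_that("joint probabilities normalize and alpha=1 is unsmoothed", {
  counts <- rsymCounts(10, seed = 4)
  cm <- CoocMatrix(counts)
  # sum of p(w,c) over unordered pairs equals 1
  N <- sum(counts) / 2
  expect_equal(sum(counts[upper.tri(counts)]) / N, 1)
  got <- as.matrix(pmiMatrix(cm, alpha = 1))
  want <- densePMIOracle(counts, 1)
  nz <- counts > 0
  expect_equal(got[nz], want[nz], tolerance = 1e-12)
  expect_error(pmiMatrix(CoocMatrix(matrix(0, 2, 2,
    dimnames = list(c("A", "B"), c("A", "B"))))), "empty input")
})

test_that("SPPMI clips at zero and shifts by log k", {
  cm <- CoocMatrix(rsymCounts(10, maxCount = 30L, seed = 1))
  pmi <- pmiMatrix(cm, alpha = 0.75)
  # k = 1: plain positive clip
  s1 <- as.matrix(sppmiValues(sppmiTransform(pmi, k = 1)))
  expect_equal(s1, pmax(as.matrix(pmi), 0), ignore_attr = TRUE)
  # a negative PMI cell maps to 0 for any k >= 1
  expect_true(any(as.matrix(pmi) < 0))
  expect_true(all(s1[as.matrix(pmi) < 0] == 0))
  # k = e subtracts exactly 1 on the log scale
  se <- as.matrix(sppmiValues(sppmiTransform(pmi, k = exp(1))))
  expect_equal(se, pmax(as.matrix(pmi) - 1, 0), ignore_attr = TRUE)
  expect_error(sppmiTransform(pmi, k = 0.5), "invalid shift")
})

test_that("SPPMI is cell-wise nonincreasing in k", {
  cm <- CoocMatrix(rsymCounts(10, seed = 11))
  pmi <- pmiMatrix(cm)
  prev <- as.matrix(sppmiValues(sppmiTransform(pmi, k = 1)))
  for (k in c(2, 5, 15)) {
    cur <- as.matrix(sppmiValues(sppmiTransform(pmi, k = k)))
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("full-rank symmetric scaling reconstructs the SPPMI matrix", {
  sp <- sppmiMatrix(CoocMatrix(rsymCounts(12, seed = 2)))
  f <- svdEmbeddings(sp, d = 12, sigmaPower = 0.5)$factorization
  X <- as.matrix(sppmiValues(sp))
  expect_lt(max(abs(f$Wtilde %*% t(f$Ctilde) - X)), 1e-8)
  # singular values nonnegative, nonincreasing; factors orthonormal
  expect_true(all(diff(f$d) <= 1e-12) && all(f$d >= 0))
  expect_lt(max(abs(crossprod(f$u) - diag(12))), 1e-8)
  expect_lt(max(abs(crossprod(f$v) - diag(12))), 1e-8)
})

test_that("SVD of a diagonal-structure matrix recovers the diagonal", {
  vals <- Matrix::sparseMatrix(i = 1:2, j = 1:2, x = c(4, 1), dims = c(2, 2),
                               dimnames = list(c("C1", "C2"), c("C1", "C2")))
  sp <- new("SPPMIMatrix", values = vals, vocab = c("C1", "C2"),
            alpha = 0.75, k = 1)
  f <- svdEmbeddings(sp, d = 2)$factorization
  expect_equal(f$d, c(4, 1), tolerance = 1e-12)
})

test_that("embedding shape and rank bounds are enforced", {
  sp <- sppmiMatrix(CoocMatrix(rsymCounts(9, seed = 3)))
  for (d in c(1L, 4L, 9L)) {
    emb <- svdEmbeddings(sp, d = d)$embedding
    expect_identical(dim(embeddingVectors(emb)), c(9L, d))
    expect_identical(vocabulary(emb), vocabulary(sp))
  }
  expect_error(svdEmbeddings(sp, d = 10), "invalid rank")
  expect_error(svdEmbeddings(sp, d = 0), "invalid rank")
})

test_that("reconstruction error is nonincreasing in rank (Eckart-Young)", {
  sp <- sppmiMatrix(CoocMatrix(rsymCounts(14, density = 0.5, seed = 8)))
  X <- as.matrix(sppmiValues(sp))
  errs <- vapply(c(2L, 5L, 9L, 14L), function(d) {
    f <- svdEmbeddings(sp, d = d, sigmaPower = 0.5)$factorization
    max(abs(f$Wtilde %*% t(f$Ctilde) - X))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("PCA baseline factorizes the raw counts", {
  counts <- rsymCounts(8, seed = 13)
  cm <- CoocMatrix(counts)
  # rank-recovery on the raw matrix: full rank reconstructs
  emb <- pcaEmbeddings(cm, d = 8)
  f <- svd(as.matrix(coocCounts(cm)))
  expect_lt(max(abs(abs(embeddingVectors(emb)) -
                    abs(sweep(f$u, 2, f$d, "*")))), 1e-8)
  expect_error(pcaEmbeddings(cm, d = 0), "invalid rank")
})

test_that("clustered corpora embed with higher within-cluster cosine", {
  spec <- syntheticSpec(nConcepts = 40L, nClusters = 2L, nDocuments = 80L,
                        nPlantedPairs = 0L, seed = 21L)
  parts <- pipelineEmbedding(spec, d = 10L)
  U <- embeddingVectors(parts$embedding)
  U <- U / sqrt(rowSums(U^2))
  cl <- parts$typeMap[rownames(U)]
  S <- U %*% t(U)
  same <- outer(cl, cl, "==") & upper.tri(S)
  diff <- (!outer(cl, cl, "==")) & upper.tri(S)
  expect_gt(mean(S[same]), mean(S[diff]))
})
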