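test_that("text co-occurrence counts presence once per window", {
  cm <- textCooccurrence(list(c("A", "B"), c("A", "B"), c("A", "C")),
                         vocab = c("A", "B", "C"))
  cts <- coocCounts(cm)
  expect_equal(cts["A", "B"], 2)
  expect_equal(cts["A", "C"], 1)
  expect_equal(cts["B", "C"], 0)
  # single-concept window contributes nothing
  expect_equal(sum(coocCounts(textCooccurrence(list("A"), c("A", "B")))), 0)
  # multiplicity collapsed, diagonal excluded
  cm2 <- textCooccurrence(list(c("A", "A", "B")), vocab = c("A", "B"))
  expect_equal(coocCounts(cm2)["A", "B"], 1)
  expect_equal(coocCounts(cm2)["A", "A"], 0)
})

test_that("product multiplicity counts token products", {
  cm <- textCooccurrence(list(c("A", "A", "B")), vocab = c("A", "B"),
                         multiplicity = "product")
  expect_equal(coocCounts(cm)["A", "B"], 2)
})

test_that("residual tokens are skipped by default but rejected when conceptOnly is off", {
  w <- list(c("A", "noise", "B"))
  expect_equal(coocCounts(textCooccurrence(w, c("A", "B")))["A", "B"], 1)
  expect_error(textCooccurrence(w, c("A", "B"), conceptOnly = FALSE),
               "vocabulary mismatch")
})

test_that("total text count equals sum of per-window pair counts", {
  set.seed(3)
  vocab <- sprintf("C%07d", 1:12)
  for (trial in 1:10) {
    wins <- replicate(15, sample(vocab, sample(1:8, 1), replace = TRUE),
                      simplify = FALSE)
    cm <- textCooccurrence(wins, vocab)
    expected <- sum(vapply(wins, function(w) choose(length(unique(w)), 2),
                           numeric(1)))
    expect_equal(sum(coocCounts(cm)) / 2, expected)
  }
})

test_that("rolling temporal counting respects the day span", {
  v <- c("C0000001", "C0000002")
  near <- data.frame(patient_id = "p1", cui = v, day = c(0L, 25L))
  far <- data.frame(patient_id = "p1", cui = v, day = c(0L, 40L))
  expect_equal(coocCounts(temporalCooccurrence(near, v, 30))[1, 2], 1)
  expect_equal(coocCounts(temporalCooccurrence(far, v, 30))[1, 2], 0)
  # pairs never cross patients
  split2 <- data.frame(patient_id = c("p1", "p2"), cui = v, day = c(0L, 0L))
  expect_equal(sum(coocCounts(temporalCooccurrence(split2, v, 30))), 0)
  # empty stream -> all-zero matrix
  empty <- data.frame(patient_id = character(), cui = character(),
                      day = integer())
  expect_equal(sum(coocCounts(temporalCooccurrence(empty, v, 30))), 0)
})

test_that("temporal counting validates inputs", {
  v <- c("C0000001", "C0000002")
  ev <- data.frame(patient_id = "p1", cui = c("C0000001", "C0000009"),
                   day = c(0L, 1L))
  expect_error(temporalCooccurrence(ev, v, 30), "vocabulary mismatch")
  expect_error(temporalCooccurrence(ev, v, -5), "invalid parameter")
})

test_that("calendar bins anchor at each patient's first event", {
  v <- c("C0000001", "C0000002")
  # days 35 and 55 share a bin once anchored at 35, though they
  # straddle a bin edge anchored at zero
  ev <- data.frame(patient_id = "p1", cui = v, day = c(35L, 55L))
  expect_equal(coocCounts(temporalCooccurrence(ev, v, 30, "calendar"))[1, 2], 1)
  # same days, bin boundary between them relative to first event
  ev2 <- data.frame(patient_id = "p1", cui = v, day = c(35L, 70L))
  expect_equal(coocCounts(temporalCooccurrence(ev2, v, 30, "calendar"))[1, 2], 0)
})

test_that("perPeriod calendar counting adds per-bin multiplicity", {
  v <- c("C0000001", "C0000002")
  ev <- data.frame(patient_id = "p1",
                   cui = rep(v, 2L), day = c(0L, 5L, 40L, 45L))
  expect_equal(coocCounts(temporalCooccurrence(ev, v, 30, "calendar"))[1, 2], 1)
  expect_equal(coocCounts(temporalCooccurrence(
    ev, v, 30, "calendar", perPeriod = TRUE))[1, 2], 2)
})

test_that("merge unions vocabularies and sums aligned cells", {
  a <- textCooccurrence(list(c("A", "B")), vocab = c("A", "B"))
  b <- textCooccurrence(list(c("B", "C"), c("B", "C")), vocab = c("B", "C"))
  m <- mergeCooccurrence(list(a, b))
  expect_identical(vocabulary(m), c("A", "B", "C"))
  expect_equal(coocCounts(m)["A", "B"], 1)
  expect_equal(coocCounts(m)["B", "C"], 2)
  expect_equal(coocCounts(m)["A", "C"], 0)
  # self-merge doubles every cell
  mm <- mergeCooccurrence(list(a, a))
  expect_equal(as.matrix(coocCounts(mm)), 2 * as.matrix(coocCounts(a)),
               ignore_attr = TRUE)
  # disjoint vocabularies -> block diagonal
  d <- textCooccurrence(list(c("X", "Y")), vocab = c("X", "Y"))
  bd <- mergeCooccurrence(list(a, d))
  expect_equal(coocCounts(bd)["A", "X"], 0)
  expect_error(mergeCooccurrence(list()), "nothing to merge")
})

test_that("merge is commutative and associative", {
  a <- textCooccurrence(list(c("A", "B")), vocab = c("A", "B"))
  b <- textCooccurrence(list(c("B", "C")), vocab = c("B", "C"))
  c3 <- textCooccurrence(list(c("A", "C"), c("A", "C")), vocab = c("A", "C"))
  ab <- mergeCooccurrence(list(a, b))
  ba <- mergeCooccurrence(list(b, a))
  expect_equal(as.matrix(coocCounts(ab)), as.matrix(coocCounts(ba)))
  lhs <- mergeCooccurrence(list(mergeCooccurrence(list(a, b)), c3))
  rhs <- mergeCooccurrence(list(a, mergeCooccurrence(list(b, c3))))
  expect_equal(as.matrix(coocCounts(lhs)), as.matrix(coocCounts(rhs)))
})

test_that("symmetry and zero diagonal hold after every operation", {
  set.seed(9)
  vocab <- sprintf("C%07d", 1:8)
  wins <- replicate(10, sample(vocab, sample(2:6, 1), replace = TRUE),
                    simplify = FALSE)
  ev <- randomEventStream(12, 6, 8, seed = 2)
  mats <- list(textCooccurrence(wins, vocab),
               temporalCooccurrence(ev, vocab, 30, "rolling"),
               temporalCooccurrence(ev, vocab, 30, "calendar"))
  mats$merged <- mergeCooccurrence(mats)
  for (m in mats) {
    cts <- as.matrix(coocCounts(m))
    expect_identical(cts, t(cts))
    expect_true(all(diag(cts) == 0))
    expect_true(all(cts >= 0))
  }
})

test_that("CoocMatrix validity rejects malformed content", {
  m <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(CoocMatrix(m), "symmetric")
  md <- matrix(c(1, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(CoocMatrix(md), "diagonal")
})
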