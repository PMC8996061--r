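test_that("coverage chunking always reaches every point", {
  # degenerate: k >= n gives one chunk; n = 1 gives one singleton
  cl <- randomCloud(20, seed = 1)
  expect_length(coverCloud(cl, k = 50, seed = 1), 1)
  single <- LabeledPointCloud(matrix(0, 1, 3), matrix(0L, 1, 3), 0L)
  cc <- coverCloud(single, k = 1, seed = 1)
  expect_length(cc, 1)
  expect_equal(memberIndices(cc[[1]]), 1L)

  cl <- randomCloud(5000, seed = 2)
  chunks <- coverCloud(cl, k = 256, seed = 3)
  expect_setequal(sort(unique(unlist(lapply(chunks, memberIndices)))), 1:5000)
  expect_lte(length(chunks), 5000)          # terminates in <= n iterations
  expect_lt(length(chunks), 5000 / 10)      # and in practice far fewer
  # identical under the same seed
  expect_identical(lapply(coverCloud(cl, k = 256, seed = 3), memberIndices),
                   lapply(chunks, memberIndices))
})

test_that("batched coverage still covers everything", {
  cl <- randomCloud(2000, seed = 4)
  chunks <- coverCloud(cl, k = 128, seed = 5, batchSize = 8)
  expect_setequal(sort(unique(unlist(lapply(chunks, memberIndices)))), 1:2000)
})

test_that("majority voting resolves strict majorities and flags coverage gaps", {
  # single full prediction: identity
  pred <- list(list(memberIndices = 1:4, labels = c(0L, 1L, 2L, 3L)))
  tally <- mergePredictions(4, pred, seed = 1)
  expect_equal(tally@labels, c(0L, 1L, 2L, 3L))
  expect_false(any(tally@tie))

  # votes (leaf, leaf, stem) -> leaf
  preds <- list(list(memberIndices = 1L, labels = 2L),
                list(memberIndices = 1L, labels = 2L),
                list(memberIndices = 1L, labels = 0L))
  expect_equal(mergePredictions(1, preds, seed = 1)@labels, 2L)

  # vote conservation: per-point votes sum to the number of covering chunks
  set.seed(6)
  preds <- lapply(1:20, function(i) {
    mi <- sort(sample(50, 25))
    list(memberIndices = mi, labels = sample(0:7, 25, replace = TRUE))
  })
  cover <- tabulate(unlist(lapply(preds, `[[`, "memberIndices")), 50)
  if (any(cover == 0)) {
    expect_error(mergePredictions(50, preds, seed = 1), "without any prediction")
  } else {
    tally <- mergePredictions(50, preds, seed = 1)
    expect_equal(unname(rowSums(tally@votes)), cover)
    expect_true(all(tally@votes[cbind(1:50, tally@labels + 1L)] ==
                    apply(tally@votes, 1, max)))
  }
  partial <- list(list(memberIndices = 1:5, labels = rep(0L, 5)))
  expect_error(mergePredictions(10, partial, seed = 1), "without any prediction")
})

test_that("tie-breaking is seeded and merges without ties are seed-independent", {
  tiePred <- list(list(memberIndices = 1L, labels = 0L),
                  list(memberIndices = 1L, labels = 2L))
  r1 <- mergePredictions(1, tiePred, seed = 7)@labels
  r2 <- mergePredictions(1, tiePred, seed = 7)@labels
  expect_identical(r1, r2)
  expect_true(mergePredictions(1, tiePred, seed = 7)@tie)

  noTie <- list(list(memberIndices = 1:3, labels = c(1L, 1L, 5L)),
                list(memberIndices = 1:3, labels = c(1L, 1L, 5L)))
  expect_identical(mergePredictions(3, noTie, seed = 1)@labels,
                   mergePredictions(3, noTie, seed = 999)@labels)
})

test_that("agreeing chunk predictions reconstruct the ground truth exactly", {
  cl <- generatePlant(plantParams(nPoints = 3000, seed = 9))
  chunks <- coverCloud(cl, k = 200, seed = 10)
  preds <- lapply(chunks, function(ch)
    list(memberIndices = memberIndices(ch),
         labels = pointLabels(cl)[memberIndices(ch)]))
  tally <- mergePredictions(nPoints(cl), preds, seed = 11)
  expect_identical(tally@labels, pointLabels(cl))
})
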