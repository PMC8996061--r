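makeColourChunkView <- function(n = 200, seed = 1) {
  # two spatially mixed classes with cleanly separated colours
  set.seed(seed)
  labels <- rep(c(0L, 2L), each = n / 2)
  colours <- matrix(0L, n, 3)
  colours[labels == 0L, ] <- matrix(sample(200:255, 3 * n / 2, TRUE), ncol = 3)
  colours[labels == 2L, ] <- matrix(sample(0:55, 3 * n / 2, TRUE), ncol = 3)
  list(positions = matrix(rnorm(3 * n, sd = 10), ncol = 3),
       colours = colours, labels = labels,
       memberIndices = 1:n, anchorIndex = 1L)
}

test_that("the baseline separates colour-distinct classes almost perfectly", {
  v <- makeColourChunkView()
  model <- fitSegmenter(baselineSegmenter(), list(v))
  pred <- predictSegmenter(model, v)
  expect_gte(mean(pred == v$labels), 0.99)
  expect_true(all(pred %in% c(0L, 2L)))
})

test_that("fitting and prediction are deterministic and validly shaped", {
  pl <- generatePlant(plantParams(nPoints = 4000, seed = 55))
  ts <- buildTrainingSet(pl, "class_dependent", a = 16, k = 128, seed = 3)
  views <- chunkViews(pl, ts$chunks[[1]])
  m1 <- fitSegmenter(baselineSegmenter(), views)
  m2 <- fitSegmenter(baselineSegmenter(), views)
  expect_identical(m1@centroids, m2@centroids)
  p1 <- predictSegmenter(m1, views[[5]])
  expect_identical(p1, predictSegmenter(m1, views[[5]]))
  expect_length(p1, length(views[[5]]$labels))
  expect_true(all(p1 >= 0 & p1 < 8))
})

test_that("indistinguishable classes sit at the coin-flip floor", {
  n <- 400
  feat <- matrix(rnorm(3 * n), ncol = 3)[rep(1:(n / 2), 2), ]  # duplicated
  v <- list(positions = feat,
            colours = matrix(100L, n, 3),
            labels = rep(c(0L, 1L), each = n / 2),
            memberIndices = 1:n, anchorIndex = 1L)
  model <- fitSegmenter(baselineSegmenter(), list(v))
  acc <- mean(predictSegmenter(model, v) == v$labels)
  expect_gte(acc, 0.4)
  expect_lte(acc, 0.6)
})

test_that("single-class training data is rejected; unseen chunks still classify", {
  v <- makeColourChunkView()
  v$labels <- rep(3L, length(v$labels))
  expect_error(fitSegmenter(baselineSegmenter(), list(v)), "at least 2 classes")

  model <- fitSegmenter(baselineSegmenter(), list(makeColourChunkView()))
  far <- makeColourChunkView(seed = 2)
  far$positions <- far$positions + 1e5   # far from anything seen in training
  pred <- predictSegmenter(model, far)
  expect_true(all(pred %in% model@classes))  # nearest centroid always exists
})

test_that("prediction agrees with a brute-force distance-to-centroid oracle", {
  pl <- generatePlant(plantParams(nPoints = 4000, seed = 66))
  ts <- buildTrainingSet(pl, "class_dependent", a = 20, k = 64, seed = 4)
  views <- chunkViews(pl, ts$chunks[[1]])
  model <- fitSegmenter(baselineSegmenter(), views)
  feats <- phytochunk:::viewFeatures  # features are shared; the oracle checks
  for (v in views[1:20]) {            # the nearest-centroid assignment itself
    std <- sweep(sweep(feats(v, model@kLocal), 2, model@featureMean),
                 2, model@featureSd, "/")
    oracle <- apply(std, 1, function(row) {
      d2 <- rowSums(sweep(model@centroids, 2, row)^2)
      model@classes[which.min(d2)]
    })
    expect_identical(predictSegmenter(model, v), unname(oracle))
  }
})
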