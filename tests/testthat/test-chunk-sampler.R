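test_that("anchor allocation reproduces the frozen worked examples", {
  # symmetric: uniform 8 classes, a = 80 -> 10 each, both strategies
  u <- ClassDistribution(rep(10, 8))
  expect_equal(unname(anchorsPerClass(allocateAnchorsIndependent(u, 80))), rep(10L, 8))
  expect_equal(unname(anchorsPerClass(allocateAnchorsDependent(u, 80))), rep(10L, 8))

  # the printed imbalanced profile at a = 100 (frozen from the brute-force
  # largest-remainder oracle over raw quotas 2.7, 1.5, 78.9, 0.475 x 4, 15.0)
  d <- ClassDistribution(referenceFractions() * 200000)
  ind <- anchorsPerClass(allocateAnchorsIndependent(d, 100))
  expect_equal(unname(ind), c(3L, 2L, 79L, 1L, 0L, 0L, 0L, 15L))
  expect_equal(sum(ind), 100)
  expect_true(inAllocSet(ind, oracleLargestRemainder(classFractions(d) * 100, 100)))

  # inverse allocation: raw quotas 13.9, 14.07, 3.01, 14.22 x 4, 12.14
  dep <- anchorsPerClass(allocateAnchorsDependent(d, 100))
  expect_equal(sum(dep), 100)
  expect_true(inAllocSet(dep, oracleLargestRemainder(
    (1 - classFractions(d)) / sum(1 - classFractions(d)) * 100, 100)))
  expect_equal(names(which.min(dep)), "leaf")  # leaf gets fewest anchors

  # degenerate cases
  single <- ClassDistribution(c(0, 0, 50, 0, 0, 0, 0, 0))
  expect_equal(unname(anchorsPerClass(allocateAnchorsIndependent(single, 100))),
               c(0L, 0L, 100L, 0L, 0L, 0L, 0L, 0L))
  expect_error(allocateAnchorsDependent(single, 100), "2 present classes")

  two <- ClassDistribution(c(90, 10), ClassScheme(c("a", "b")))
  expect_equal(unname(anchorsPerClass(allocateAnchorsDependent(two, 100))),
               c(10L, 90L))
  expect_error(allocateAnchorsIndependent(d, 0), "a must be")
})

test_that("allocation sums to a, matches the oracle, and is proportional-equal on uniforms", {
  for (s in 1:100) {
    set.seed(s)
    C <- sample(2:10, 1)
    counts <- rmultinom(1, sample(50:5000, 1), rexp(C) + 0.05)[, 1]
    counts[1] <- counts[1] + 1  # ensure at least one present class
    d <- ClassDistribution(counts, ClassScheme(paste0("c", 1:C)))
    a <- sample(1:300, 1)
    p <- classFractions(d)
    ind <- anchorsPerClass(allocateAnchorsIndependent(d, a))
    expect_equal(sum(ind), a)
    expect_true(inAllocSet(ind, oracleLargestRemainder(p * a, a)))
    if (sum(counts > 0) >= 2) {
      dep <- anchorsPerClass(allocateAnchorsDependent(d, a))
      expect_equal(sum(dep), a)
      inv <- ifelse(counts > 0, 1 - p, 0)
      expect_true(inAllocSet(dep, oracleLargestRemainder(inv / sum(inv) * a, a)))
      expect_true(all(dep[counts == 0] == 0))
    }
  }
})

test_that("anchor sampling is exhaustive, seeded and uniform", {
  cl <- randomCloud(40, seed = 8, C = 4)
  d <- classDistribution(cl)
  plan <- allocateAnchorsIndependent(d, 40)  # a_c = n_c: draw everything
  anchors <- sampleAnchorPoints(cl, plan, seed = 1)
  expect_setequal(anchors$index, 1:40)
  expect_equal(anchors$class, pointLabels(cl)[anchors$index])

  a1 <- sampleAnchorPoints(cl, allocateAnchorsIndependent(d, 10), seed = 42)
  a2 <- sampleAnchorPoints(cl, allocateAnchorsIndependent(d, 10), seed = 42)
  expect_identical(a1, a2)

  # uniformity: single-class 10-point cloud, one anchor, 10,000 seeded draws
  tiny <- LabeledPointCloud(matrix(runif(30), 10), matrix(0L, 10, 3), rep(0L, 10))
  plan1 <- allocateAnchorsIndependent(classDistribution(tiny), 1)
  draws <- vapply(1:10000, function(s)
    sampleAnchorPoints(tiny, plan1, seed = s)$index, integer(1))
  freq <- tabulate(draws, 10) / 10000
  expect_true(all(abs(freq - 0.1) <= 0.01))
})

test_that("oversampling a small class falls back to with-replacement with a warning", {
  cl <- LabeledPointCloud(matrix(runif(30), 10), matrix(0L, 10, 3),
                          c(rep(0L, 8), 1L, 1L))
  plan <- new("SamplingPlan", strategy = "class_dependent",
              anchorsPerClass = setNames(c(0L, 5L, rep(0L, 6)),
                                         classNames(defaultClassScheme())),
              k = NA_integer_, scheme = defaultClassScheme())
  expect_warning(a <- sampleAnchorPoints(cl, plan, seed = 1), "replacement")
  expect_equal(nrow(a), 5)
  expect_true(all(a$index %in% 9:10))
})

test_that("extractChunk matches forced tie-break and the brute-force oracle", {
  # 5 collinear points at x = 0..4, anchor the middle one, k = 3:
  # distances {2,1,0,1,2}; ties resolve to the lower index
  line <- LabeledPointCloud(cbind(0:4, 0, 0), matrix(0L, 5, 3), rep(0L, 5))
  ch <- extractChunk(line, 3, 3)
  expect_identical(memberIndices(ch), c(3L, 2L, 4L))

  # k >= n: the whole cloud
  expect_setequal(memberIndices(extractChunk(line, 1, 99)), 1:5)
  expect_error(extractChunk(line, 1, 0), "k must be")

  for (s in 1:30) {
    cl <- randomCloud(sample(50:1000, 1), seed = 900 + s)
    anc <- sample(nPoints(cl), 1)
    k <- sample(nPoints(cl), 1)
    expect_identical(memberIndices(extractChunk(cl, anc, k)),
                     oracleKnn(positions(cl), anc, k))
  }
})

test_that("buildTrainingSet produces a chunks per cloud and favours balance", {
  pl <- generatePlant(plantParams(nPoints = 2000, seed = 17))
  one <- buildTrainingSet(pl, "class_dependent", a = 1, k = 64, seed = 1)
  expect_equal(length(one$chunks[[1]]), 1)

  clouds <- lapply(1:3, function(i)
    generatePlant(plantParams(nPoints = 2000, seed = 20 + i), sprintf("p%d", i)))
  ts <- buildTrainingSet(clouds, "class_independent", a = 25, k = 128, seed = 4)
  expect_equal(sum(lengths(ts$chunks)), 75)  # a chunks per cloud
  expect_true(all(vapply(ts$chunks[[2]], function(ch)
    length(memberIndices(ch)) == 128, logical(1))))

  # manifests written and re-readable
  dir <- withr::local_tempdir()
  ts2 <- buildTrainingSet(clouds[[1]], "class_dependent", a = 5, k = 32,
                          seed = 9, manifestDir = dir)
  back <- readChunkSet(file.path(dir, "p1_chunks.json"))
  expect_equal(length(back$chunks), 5)
  expect_identical(memberIndices(back$chunks[[3]]),
                   memberIndices(ts2$chunks[[1]][[3]]))
})
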