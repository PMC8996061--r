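test_that("a hand-written ASCII PLY with labels round-trips", {
  ply <- c("ply", "format ascii 1.0", "element vertex 3",
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green", "property uchar blue",
           "property int scalar_label", "end_header",
           "0 0 0 10 20 30 0",
           "1 0 0 11 21 31 2",
           "0 1 0 12 22 32 2")
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(ply, f)
  cl <- readCloud(f)
  expect_equal(nPoints(cl), 3)
  expect_equal(pointLabels(cl), c(0L, 2L, 2L))
  expect_equal(positions(cl)[2, ], c(1, 0, 0))
  expect_equal(pointColours(cl)[3, ], c(12L, 22L, 32L))
})

test_that("a 6-column table yields an all-unlabelled cloud; 7 columns are labels", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 0 1 2 3", "1 1 1 4 5 6"), f)
  cl <- readCloud(f)
  expect_true(all(is.na(pointLabels(cl))))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0,0,1,2,3,5", "1,1,1,4,5,6,-1"), f2)
  cl2 <- readCloud(f2)
  expect_equal(pointLabels(cl2), c(5L, NA_integer_))
})

test_that("write/read round trip preserves a 1000-point synthetic cloud", {
  cl <- generatePlant(plantParams(nPoints = 1000, seed = 3), "rt")
  for (fmt in c("ply_ascii", "xyz_table")) {
    f <- withr::local_tempfile(fileext = if (fmt == "ply_ascii") ".ply" else ".txt")
    writeCloud(cl, f, format = fmt)
    back <- readCloud(f, format = fmt, cloudId = "rt")
    expect_equal(positions(back), positions(cl), tolerance = 1e-6)
    expect_identical(pointColours(back), pointColours(cl))
    expect_identical(pointLabels(back), pointLabels(cl))
  }
})

test_that("an unlabelled cloud writes 6 columns, a labelled one 7", {
  pos <- matrix(runif(9), 3)
  col <- matrix(1L, 3, 3)
  f <- withr::local_tempfile()
  writeCloud(LabeledPointCloud(pos, col), f, format = "xyz_table")
  expect_equal(ncol(utils::read.table(f)), 6)
  writeCloud(LabeledPointCloud(pos, col, c(0L, NA, 1L)), f, format = "xyz_table")
  tab <- utils::read.table(f)
  expect_equal(ncol(tab), 7)
  expect_equal(tab[[7]], c(0L, -1L, 1L))  # -1 is the on-disk sentinel
})

test_that("malformed inputs raise format errors naming the problem", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("not_ply", "junk"), f)
  expect_error(readCloud(f), "magic")

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 0 1 2 3 9"), f2)  # label 9 >= C = 8
  expect_error(readCloud(f2), "outside 0..7")

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 0 1 2", "0 0 0 1 2 3 4 5"), f3)  # ragged/wrong arity
  expect_error(readCloud(f3))
})

test_that("chunk manifests round-trip losslessly and bounds-check members", {
  f <- withr::local_tempfile(fileext = ".json")
  one <- Chunk(1, 1, k = 1, anchorClass = 4L)
  writeChunkSet(list(one), "c1", f, nPoints = 1)
  back <- readChunkSet(f)
  expect_equal(back$cloudId, "c1")
  expect_equal(length(back$chunks), 1)
  expect_equal(memberIndices(back$chunks[[1]]), 1L)
  expect_equal(anchorClass(back$chunks[[1]]), 4L)

  set.seed(1)
  chunks <- lapply(1:100, function(i) {
    anc <- sample(500, 1)
    Chunk(anc, unique(c(anc, sample(500, 19))), k = 20)
  })
  writeChunkSet(chunks, "big", f, nPoints = 500)
  back <- readChunkSet(f)$chunks
  for (i in seq_along(chunks)) {
    expect_identical(memberIndices(back[[i]]), memberIndices(chunks[[i]]))
    expect_identical(anchorIndex(back[[i]]), anchorIndex(chunks[[i]]))
    expect_identical(back[[i]]@k, chunks[[i]]@k)
  }

  bad <- Chunk(1, c(1L, 105L), k = 2)
  expect_error(writeChunkSet(list(bad), "small", f, nPoints = 100), "exceeds")
  writeChunkSet(list(bad), "small", f)          # unknown n: written as-is
  expect_error(readChunkSet(f, nPoints = 100), "exceeds")
})
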