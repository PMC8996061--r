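test_that("confusion matrices tally points exactly", {
  # perfect prediction: purely diagonal, normalised diagonal 100
  t_ <- rep(0:7, times = 8:1)
  cmP <- confusionMatrix(t_, t_)
  expect_true(all(confusionCounts(cmP)[upper.tri(confusionCounts(cmP))] == 0))
  expect_equal(unname(diag(normalisedPercent(cmP))), rep(100, 8))

  # everything predicted as one class: a single non-zero column
  cmC <- confusionMatrix(t_, rep(2L, length(t_)))
  expect_true(all(confusionCounts(cmC)[, -3] == 0))

  set.seed(11)
  tt <- sample(0:7, 10000, replace = TRUE)
  pp <- sample(0:7, 10000, replace = TRUE)
  cm <- confusionMatrix(tt, pp)
  o <- oracleTally(tt, pp, 8)
  f <- list(tp = diag(confusionCounts(cm)),
            fp = colSums(confusionCounts(cm)) - diag(confusionCounts(cm)),
            fn = rowSums(confusionCounts(cm)) - diag(confusionCounts(cm)))
  expect_equal(unname(f$tp), o$tp)
  expect_equal(unname(f$fp), o$fp)
  expect_equal(unname(f$fn), o$fn)
  expect_equal(unname(rowSums(normalisedPercent(cm))), rep(100, 8),
               tolerance = 1e-9)
  expect_error(confusionMatrix(0:3, 0:2), "equal length")
  expect_error(confusionMatrix(c(0L, NA), c(0L, 1L)), "fully labelled")
})

test_that("IoU follows its closed forms and the set-theoretic oracle", {
  # TP 5, FP 3, FN 2 -> 0.5, built from explicit label vectors
  tt <- c(rep(0, 5), rep(0, 2), rep(1, 3), rep(1, 10))
  pp <- c(rep(0, 5), rep(1, 2), rep(0, 3), rep(1, 10))
  cm <- confusionMatrix(tt, pp, ClassScheme(c("a", "b")))
  expect_equal(unname(iouPerClass(cm))[1], 0.5)

  for (s in 1:20) {
    set.seed(s)
    n <- sample(100:2000, 1)
    tt <- sample(0:7, n, replace = TRUE)
    pp <- sample(0:7, n, replace = TRUE)
    cm <- confusionMatrix(tt, pp)
    expect_equal(unname(iouPerClass(cm)), oracleIouFromLabels(tt, pp, 8))
    pr <- precisionRecall(cm)
    o <- oracleTally(tt, pp, 8)
    expect_equal(unname(pr$precision), ifelse(o$tp + o$fp > 0,
                                              o$tp / (o$tp + o$fp), NaN))
    expect_equal(unname(pr$recall), ifelse(o$tp + o$fn > 0,
                                           o$tp / (o$tp + o$fn), NaN))
    # identity IoU = PR / (P + R - PR) where defined and non-zero
    ok <- !is.nan(pr$precision) & !is.nan(pr$recall) &
      pr$precision > 0 & pr$recall > 0
    expect_equal(iouPerClass(cm)[ok],
                 (pr$precision * pr$recall /
                    (pr$precision + pr$recall - pr$precision * pr$recall))[ok])
    # micro IoU is permutation invariant; IoU_c <= min(P_c, R_c)
    perm <- sample(0:7)
    expect_equal(iouMicro(confusionMatrix(perm[tt + 1], perm[pp + 1])),
                 iouMicro(cm))
    expect_true(all(iouPerClass(cm)[ok] <= pmin(pr$precision, pr$recall)[ok] + 1e-12))
  }
})

test_that("micro pools counts while macro weighs classes equally", {
  tt <- rep(0:1, times = c(98, 2))
  pp <- c(rep(0L, 98), 0L, 0L)  # majority perfect, minority all wrong
  cm <- confusionMatrix(tt, pp, ClassScheme(c("maj", "min")))
  # pooled denominator counts each error twice (FP of one class, FN of the
  # other): micro = 98 / (98 + 2 + 2)
  expect_equal(iouMicro(cm), 98 / 102)
  expect_equal(iouMacro(cm), mean(c(98 / 100, 0)))
  expect_gt(iouMicro(cm), iouMacro(cm))

  # equal-size classes with IoUs (1, 0) -> macro 0.5
  expect_equal(iouMacro(c(1, 0)), 0.5)
  # undefined values are excluded, not zeroed
  expect_equal(suppressMessages(iouMacro(c(0.6, NaN, 0.4))), 0.5)
  # perfect prediction: micro = macro = 1
  cmP <- confusionMatrix(0:7, 0:7)
  expect_equal(iouMicro(cmP), 1)
  expect_equal(iouMacro(cmP), 1)
})

test_that("normalised-difference matrices behave like the printed comparison", {
  ref <- cucumberReferenceTables()
  d <- diffNormalised(ref$independent, ref$dependent)
  expect_equal(d["node", "node"], 46.0)
  expect_true(all(abs(rowSums(d)) <= 0.1 + 1e-9))  # rows each sum to ~0

  set.seed(3)
  tt <- sample(0:7, 500, replace = TRUE)
  cm <- confusionMatrix(tt, sample(0:7, 500, replace = TRUE))
  expect_true(all(diffNormalised(cm, cm) == 0))
  small <- ClassScheme(c("a", "b"))
  cm2 <- confusionMatrix(c(0, 1), c(0, 1), small)
  expect_error(diffNormalised(cm, cm2), "different class schemes")
})

test_that("recall equals the row-normalised diagonal of the reference matrices", {
  ref <- cucumberReferenceTables()
  for (strat in c("class_independent", "class_dependent")) {
    mat <- if (strat == "class_independent") ref$independent else ref$dependent
    printed <- ref$precisionRecall$R[ref$precisionRecall$strategy == strat]
    expect_equal(roundHalfUp(unname(diag(mat)) / 100, 2), printed)
  }
})

test_that("Wilcoxon labels follow the exact signed-rank null", {
  expect_equal(comparePaired(1:10, 1:10), list(pValue = 1, stars = "n.s."))

  # 10 pairs, all differences positive: exact two-sided p = 2 / 2^10
  cp <- comparePaired(1:10, 1:10 + seq(0.1, 1, by = 0.1))
  expect_equal(cp$pValue, 2 / 2^10)
  expect_equal(cp$stars, "**")

  # 5 positive pairs: p = 2 / 2^5 = 0.0625, just above 0.05 -> n.s.
  cp5 <- comparePaired(1:5, 1:5 + c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(cp5$pValue, 2 / 2^5)
  expect_equal(cp5$stars, "n.s.")

  # large/tied samples fall back to the normal approximation and stay valid
  set.seed(8)
  a <- rnorm(40)
  cpBig <- comparePaired(a, a + rbinom(40, 2, 0.5) - 0.3)
  expect_true(cpBig$pValue >= 0 && cpBig$pValue <= 1)
  expect_error(comparePaired(1:4, 1:4), "at least 5")
  expect_error(comparePaired(1:6, 1:5), "equal length")

  expect_equal(significanceStars(0.0005), "***")
  expect_equal(significanceStars(0.005), "**")
  expect_equal(significanceStars(0.04), "*")
  expect_equal(significanceStars(0.5), "n.s.")
})
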