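# Orchestration of the two standard experiments: sampling-strategy
# comparison at fixed k (experiment 1) and the chunk-size sweep under the
# class-dependent strategy (experiment 2).

#' Segment a full cloud with a trained model
#'
#' Coverage-chunks the cloud (class-independent: anchors are drawn from the
#' not-yet-covered points, ignoring labels), predicts every chunk, and
#' merges the overlapping predictions by majority vote. Evaluation of a
#' pipeline is always done on such merged full clouds.
#'
#' @param model a trained segmenter model.
#' @param cloud the cloud to segment.
#' @param k chunk size used for coverage chunking.
#' @param seed integer seed driving anchor selection and tie-breaking.
#' @param batchSize see \code{\link{coverCloud}}.
#' @return integer vector of predicted 0-based labels, one per point.
#' @export
predictCloud <- function(model, cloud, k, seed = NULL, batchSize = 1L) {
  chunks <- coverCloud(cloud, k, seed = if (is.null(seed)) NULL
                                        else subSeed(seed, "cover"),
                       batchSize = batchSize)
  views <- chunkViews(cloud, chunks)
  preds <- lapply(views, function(v)
    list(memberIndices = v$memberIndices,
         labels = predictSegmenter(model, v)))
  tally <- mergePredictions(nPoints(cloud), preds,
                            scheme = classScheme(cloud),
                            seed = if (is.null(seed)) NULL
                                   else subSeed(seed, "merge"))
  tally@labels
}

# one train->predict->evaluate pass; returns per-class and summary rows
runOnePass <- function(trainClouds, testClouds, strategy, a, k, seed,
                       segmenter, batchSize) {
  ts <- buildTrainingSet(trainClouds, strategy, a = a, k = k, seed = seed)
  views <- unlist(lapply(seq_along(trainClouds), function(i)
    chunkViews(trainClouds[[i]], ts$chunks[[i]])), recursive = FALSE)
  model <- fitSegmenter(segmenter, views)
  perClass <- list()
  summary_ <- list()
  for (j in seq_along(testClouds)) {
    cloud <- testClouds[[j]]
    pred <- predictCloud(model, cloud, k = k,
                         seed = subSeed(seed, "cover", j), batchSize = batchSize)
    rep_ <- evaluateSegmentation(cloud@labels, pred, classScheme(cloud))
    tab <- metricTable(rep_)
    tab$cloud <- cloud@cloudId
    perClass[[j]] <- tab
    summary_[[j]] <- data.frame(cloud = cloud@cloudId,
                                iouMicro = rep_@iouMicro,
                                iouMacro = rep_@iouMacro)
  }
  list(perClass = do.call(rbind, perClass),
       summary = do.call(rbind, summary_),
       trainingEntropy = ts$entropy,
       trainingDistribution = ts$distribution,
       chunks = ts$chunks)
}

tCI <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  if (n < 2) return(c(mean = m, lower = NA_real_, upper = NA_real_))
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
  c(mean = m, lower = m - half, upper = m + half)
}

#' Experiment 1: class-independent vs class-dependent sampling
#'
#' For each strategy and repetition: build the training set, fit the
#' segmenter, coverage-chunk and segment every test cloud, merge, and
#' evaluate on the full clouds. Reports per-class means with 95%
#' Student-t confidence intervals over repetitions and Wilcoxon signed-rank
#' significance labels per class (paired over test cloud x repetition).
#' The test set is always chunked class-independently, whatever the
#' training strategy.
#'
#' @param trainClouds,testClouds lists of labelled clouds (disjoint plants).
#' @param a anchors per training cloud (default 100).
#' @param k chunk size (default 4096).
#' @param repetitions training repetitions per strategy (default 5).
#' @param seed integer master seed; all stage seeds derive from it and are
#'   recorded in the returned manifest.
#' @param segmenter a \code{\linkS4class{Segmenter}}.
#' @param batchSize coverage batch size (see \code{\link{coverCloud}}).
#' @param outDir optional directory: per-class CSV results plus a JSON
#'   manifest (config, seeds, package version) sufficient to reproduce the
#'   run are written there.
#' @return list with \code{results} (per strategy x repetition x cloud x
#'   class: IoU, P, R), \code{overall} (micro/macro IoU rows),
#'   \code{classSummary} (per strategy x class mean + 95% CI),
#'   \code{significance} (per class: Wilcoxon p and stars for
#'   dependent vs independent IoU), \code{trainingEntropy} (bits, per
#'   strategy x repetition) and \code{manifest}.
#' @export
runExperiment1 <- function(trainClouds, testClouds, a = 100, k = 4096,
                           repetitions = 5, seed = 1L,
                           segmenter = baselineSegmenter(),
                           batchSize = 1L, outDir = NULL) {
  strategies <- c("class_independent", "class_dependent")
  results <- list(); overall <- list(); entropies <- list()
  for (s in seq_along(strategies)) {
    for (r in seq_len(repetitions)) {
      passSeed <- subSeed(seed, "experiment", s * 1000L + r)
      pass <- runOnePass(trainClouds, testClouds, strategies[s], a, k,
                         passSeed, segmenter, batchSize)
      pass$perClass$strategy <- strategies[s]
      pass$perClass$repetition <- r
      pass$summary$strategy <- strategies[s]
      pass$summary$repetition <- r
      results[[length(results) + 1L]] <- pass$perClass
      overall[[length(overall) + 1L]] <- pass$summary
      entropies[[length(entropies) + 1L]] <-
        data.frame(strategy = strategies[s], repetition = r,
                   entropy = pass$trainingEntropy)
    }
  }
  results <- do.call(rbind, results)
  overall <- do.call(rbind, overall)
  entropies <- do.call(rbind, entropies)

  classSummary <- do.call(rbind, lapply(strategies, function(s) {
    do.call(rbind, lapply(unique(results$class), function(cl) {
      x <- results$IoU[results$strategy == s & results$class == cl]
      ci <- tCI(x[!is.nan(x)])
      data.frame(strategy = s, class = cl, meanIoU = ci["mean"],
                 ciLower = ci["lower"], ciUpper = ci["upper"],
                 row.names = NULL)
    }))
  }))

  significance <- do.call(rbind, lapply(unique(results$class), function(cl) {
    key <- function(s) {
      sel <- results$strategy == s & results$class == cl
      x <- results[sel, ]
      x <- x[order(x$cloud, x$repetition), ]
      x$IoU
    }
    a_ <- key("class_independent"); b_ <- key("class_dependent")
    ok <- !is.nan(a_) & !is.nan(b_)
    if (sum(ok) >= 5) {
      cp <- comparePaired(a_[ok], b_[ok])
      data.frame(class = cl, pValue = cp$pValue, stars = cp$stars)
    } else data.frame(class = cl, pValue = NA_real_, stars = NA_character_)
  }))

  manifest <- list(experiment = 1L, strategies = strategies, a = a, k = k,
                   repetitions = repetitions, seed = seed,
                   trainClouds = vapply(trainClouds, cloudId, character(1)),
                   testClouds = vapply(testClouds, cloudId, character(1)),
                   packageVersion =
                     as.character(utils::packageVersion("phytochunk")))
  out <- list(results = results, overall = overall,
              classSummary = classSummary, significance = significance,
              trainingEntropy = entropies, manifest = manifest)
  if (!is.null(outDir)) writeExperimentOutputs(out, outDir, "experiment1")
  out
}

#' Experiment 2: chunk-size sweep under class-dependent sampling
#'
#' Runs the pipeline across the chunk-size grid (default
#' \code{c(512, 1024, 2048, 4096, 8192, 16384)}) using the class-dependent
#' strategy, and additionally reports the training-set entropy and the
#' classes-per-chunk composition per k: smaller chunks give more balanced
#' training sets (higher entropy) but less context (fewer classes per
#' chunk).
#'
#' @inheritParams runExperiment1
#' @param kGrid integer vector of chunk sizes.
#' @param holdPointBudget if TRUE, holds the point budget a*k constant
#'   instead of the anchor count: each k uses
#'   \code{max(1, round(a * kGrid[1] / k))} anchors.
#' @return list with \code{results}, \code{overall}, \code{perK} (per k:
#'   training entropy, mean classes-per-chunk, mean micro/macro IoU) and
#'   \code{manifest}.
#' @export
runExperiment2 <- function(trainClouds, testClouds,
                           kGrid = c(512L, 1024L, 2048L, 4096L, 8192L, 16384L),
                           a = 100, repetitions = 5, seed = 1L,
                           segmenter = baselineSegmenter(),
                           batchSize = 1L, holdPointBudget = FALSE,
                           outDir = NULL) {
  results <- list(); overall <- list(); perK <- list()
  for (ki in seq_along(kGrid)) {
    k <- kGrid[ki]
    aK <- if (holdPointBudget) max(1L, as.integer(round(a * kGrid[1] / k))) else a
    entropies <- numeric(repetitions)
    cpcMeans <- numeric(repetitions)
    for (r in seq_len(repetitions)) {
      passSeed <- subSeed(seed, "experiment", ki * 1000L + r)
      pass <- runOnePass(trainClouds, testClouds, "class_dependent", aK, k,
                         passSeed, segmenter, batchSize)
      pass$perClass$k <- k
      pass$perClass$repetition <- r
      pass$summary$k <- k
      pass$summary$repetition <- r
      results[[length(results) + 1L]] <- pass$perClass
      overall[[length(overall) + 1L]] <- pass$summary
      entropies[r] <- pass$trainingEntropy
      cpcMeans[r] <- mean(vapply(seq_along(trainClouds), function(i)
        chunkComposition(pass$chunks[[i]], trainClouds[[i]])@mean, numeric(1)))
    }
    ovl <- do.call(rbind, overall[(length(overall) - repetitions + 1L):length(overall)])
    perK[[ki]] <- data.frame(k = k, a = aK,
                             trainingEntropy = mean(entropies),
                             meanClassesPerChunk = mean(cpcMeans),
                             iouMicro = mean(ovl$iouMicro),
                             iouMacro = mean(ovl$iouMacro))
  }
  manifest <- list(experiment = 2L, strategy = "class_dependent",
                   kGrid = kGrid, a = a, repetitions = repetitions,
                   seed = seed, holdPointBudget = holdPointBudget,
                   trainClouds = vapply(trainClouds, cloudId, character(1)),
                   testClouds = vapply(testClouds, cloudId, character(1)),
                   packageVersion =
                     as.character(utils::packageVersion("phytochunk")))
  out <- list(results = do.call(rbind, results),
              overall = do.call(rbind, overall),
              perK = do.call(rbind, perK), manifest = manifest)
  if (!is.null(outDir)) writeExperimentOutputs(out, outDir, "experiment2")
  out
}

writeExperimentOutputs <- function(out, outDir, prefix) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  utils::write.table(out$results, file.path(outDir, paste0(prefix, "_results.csv")),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(out$overall, file.path(outDir, paste0(prefix, "_overall.csv")),
                     sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(out$manifest, file.path(outDir, paste0(prefix, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
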