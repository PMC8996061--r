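# Accessors and show() methods.

#' @rdname ClassScheme-class
#' @export
setMethod("classNames", "ClassScheme", function(x) x@classNames)

#' @rdname ClassScheme-class
#' @export
setMethod("nClasses", "ClassScheme", function(x) length(x@classNames))

#' @rdname LabeledPointCloud-class
#' @export
setMethod("nPoints", "LabeledPointCloud", function(x) nrow(x@positions))

#' @rdname ClassDistribution-class
#' @export
setMethod("nPoints", "ClassDistribution", function(x) sum(x@counts))

#' @rdname LabeledPointCloud-class
#' @export
setMethod("classScheme", "LabeledPointCloud", function(x) x@scheme)

#' @rdname ClassDistribution-class
#' @export
setMethod("classScheme", "ClassDistribution", function(x) x@scheme)

#' @rdname ConfusionMatrix-class
#' @export
setMethod("classScheme", "ConfusionMatrix", function(x) x@scheme)

#' @rdname SamplingPlan-class
#' @export
setMethod("classScheme", "SamplingPlan", function(x) x@scheme)

#' Positions, colours and labels of a cloud
#'
#' @param x a \code{\linkS4class{LabeledPointCloud}}.
#' @return \code{positions}: n x 3 numeric matrix (mm); \code{pointColours}:
#'   n x 3 integer matrix; \code{pointLabels}: integer vector of 0-based
#'   class indices with \code{NA} for unlabelled points; \code{cloudId}:
#'   the identifier string.
#' @rdname cloud-accessors
#' @export
positions <- function(x) x@positions

#' @rdname cloud-accessors
#' @export
pointColours <- function(x) x@colours

#' @rdname cloud-accessors
#' @export
pointLabels <- function(x) x@labels

#' @rdname cloud-accessors
#' @export
cloudId <- function(x) x@cloudId

#' @rdname ClassDistribution-class
#' @export
setMethod("classCounts", "ClassDistribution", function(x) x@counts)

#' @rdname ClassDistribution-class
#' @export
setMethod("classFractions", "ClassDistribution",
          function(x) x@counts / sum(x@counts))

#' @rdname Chunk-class
#' @export
setMethod("memberIndices", "Chunk", function(x) x@memberIndices)

#' @rdname Chunk-class
#' @export
setMethod("anchorIndex", "Chunk", function(x) x@anchorIndex)

#' @rdname Chunk-class
#' @export
setMethod("anchorClass", "Chunk", function(x) x@anchorClass)

#' @rdname SamplingPlan-class
#' @export
setMethod("anchorsPerClass", "SamplingPlan", function(x) x@anchorsPerClass)

#' @rdname SamplingPlan-class
#' @param x a \code{SamplingPlan}.
#' @export
samplingStrategy <- function(x) x@strategy

#' @rdname ConfusionMatrix-class
#' @export
confusionCounts <- function(x) x@counts

setMethod("show", "ClassScheme", function(object) {
  cat("ClassScheme with", nClasses(object), "classes:",
      paste(object@classNames, collapse = ", "), "\n")
})

setMethod("show", "LabeledPointCloud", function(object) {
  n <- nPoints(object)
  nl <- sum(!is.na(object@labels))
  cat(sprintf("LabeledPointCloud '%s': %d points, %d labelled (%d classes)\n",
              object@cloudId, n, nl, nClasses(object@scheme)))
})

setMethod("show", "Chunk", function(object) {
  cat(sprintf("Chunk: anchor %d (class %s), %d members (k = %d)\n",
              object@anchorIndex,
              ifelse(is.na(object@anchorClass), "NA", object@anchorClass),
              length(object@memberIndices), object@k))
})

setMethod("show", "ClassDistribution", function(object) {
  f <- classFractions(object)
  cat(sprintf("ClassDistribution over %d points, entropy %.2f bits\n",
              sum(object@counts), shannonEntropy(object)))
  print(round(f, 4))
})

setMethod("show", "SamplingPlan", function(object) {
  cat(sprintf("SamplingPlan (%s): a = %d\n", object@strategy,
              sum(object@anchorsPerClass)))
  print(object@anchorsPerClass)
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = true, cols = predicted):\n")
  print(object@counts)
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport over %d points\n", object@nPoints))
  tab <- data.frame(IoU = roundHalfUp(object@iou, 2),
                    P = roundHalfUp(object@precision, 2),
                    R = roundHalfUp(object@recall, 2))
  print(tab)
  cat(sprintf("micro IoU %.2f | macro IoU %.2f\n",
              object@iouMicro, object@iouMacro))
})

setMethod("show", "ChunkCompositionSummary", function(object) {
  cat(sprintf(paste0("Classes per chunk over %d chunks: mean %.2f, ",
                     "quartiles [%g, %g], whiskers [%g, %g], %d outlier(s)\n"),
              length(object@classesPerChunk), object@mean,
              object@lowerQuartile, object@upperQuartile,
              object@whiskerLow, object@whiskerHigh,
              length(object@outliers)))
})

setMethod("show", "VoteTally", function(object) {
  cat(sprintf("VoteTally: %d points, %d tie(s)\n",
              nrow(object@votes), sum(object@tie)))
})
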