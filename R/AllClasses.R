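# Central S4 containers. Labels are 0-based class indices (matching the
# on-disk convention of CloudCompare-style scalar labels); NA_integer_ is the
# in-memory sentinel for "unlabelled" and -1 its on-disk form.

#' Ordered set of semantic class labels
#'
#' An ordered, unique set of organ class names. The default scheme is the
#' 8-class cucumber labelling used throughout the package: stem, petiole,
#' leaf, growing_point, node, ovary, tendril, non_plant. Class indices are
#' 0-based positions in this order.
#'
#' @slot classNames character vector of unique, non-empty class names.
#' @aliases classNames nClasses
#' @export
setClass("ClassScheme", representation(classNames = "character"))

setValidity("ClassScheme", function(object) {
  nm <- object@classNames
  if (length(nm) < 1) return("scheme must contain at least one class")
  if (anyDuplicated(nm)) return("class names must be unique")
  if (any(!nzchar(nm))) return("class names must be non-empty")
  TRUE
})

#' @param classNames character vector of class names, in index order.
#' @rdname ClassScheme-class
#' @export
ClassScheme <- function(classNames) {
  new("ClassScheme", classNames = as.character(classNames))
}

#' @rdname ClassScheme-class
#' @export
defaultClassScheme <- function() {
  ClassScheme(c("stem", "petiole", "leaf", "growing_point",
                "node", "ovary", "tendril", "non_plant"))
}

#' A labelled (or unlabelled) 3D point cloud
#'
#' One plant scan: per point an x,y,z position in millimetres, an r,g,b
#' colour in 0--255, and optionally a 0-based organ class index
#' (\code{NA} = unlabelled).
#'
#' @slot positions n x 3 numeric matrix (mm), finite.
#' @slot colours n x 3 integer matrix in 0--255.
#' @slot labels integer vector of length n; values in \code{0:(C-1)} or NA.
#' @slot cloudId single character identifier.
#' @slot scheme the \code{\linkS4class{ClassScheme}}.
#' @aliases nPoints classScheme
#' @export
setClass("LabeledPointCloud",
  representation(positions = "matrix", colours = "matrix",
                 labels = "integer", cloudId = "character",
                 scheme = "ClassScheme"))

setValidity("LabeledPointCloud", function(object) {
  n <- nrow(object@positions)
  if (n < 1) return("cloud must contain at least one point")
  if (ncol(object@positions) != 3) return("positions must have 3 columns")
  if (!all(is.finite(object@positions))) return("positions contain non-finite values")
  if (!identical(dim(object@colours), c(n, 3L)))
    return("colours must be an n x 3 matrix")
  cl <- object@colours
  if (any(cl < 0 | cl > 255, na.rm = TRUE)) return("colours must lie in 0..255")
  if (length(object@labels) != n) return("labels must have length n")
  C <- length(object@scheme@classNames)
  bad <- !is.na(object@labels) & (object@labels < 0L | object@labels >= C)
  if (any(bad))
    return(sprintf("label out of range at point %d (must be in 0..%d or NA)",
                   which(bad)[1], C - 1L))
  if (length(object@cloudId) != 1) return("cloudId must be a single string")
  TRUE
})

#' @param positions,colours,labels,cloudId,scheme see slots.
#' @rdname LabeledPointCloud-class
#' @export
LabeledPointCloud <- function(positions, colours, labels = NULL,
                              cloudId = "cloud", scheme = defaultClassScheme()) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  colours <- as.matrix(colours)
  storage.mode(colours) <- "integer"
  if (is.null(labels)) labels <- rep(NA_integer_, nrow(positions))
  new("LabeledPointCloud", positions = unname(positions),
      colours = unname(colours), labels = as.integer(labels),
      cloudId = as.character(cloudId), scheme = scheme)
}

#' One training/prediction unit: an anchor point plus its k-NN members
#'
#' @slot anchorIndex 1-based index of the anchor point in the source cloud.
#' @slot anchorClass 0-based class of the anchor (NA when unlabelled).
#' @slot memberIndices 1-based member indices, nearest first (anchor included).
#' @slot k the requested neighbourhood size; \code{length(memberIndices)} is
#'   \code{min(k, n)}.
#' @aliases memberIndices anchorIndex anchorClass
#' @export
setClass("Chunk",
  representation(anchorIndex = "integer", anchorClass = "integer",
                 memberIndices = "integer", k = "integer"))

setValidity("Chunk", function(object) {
  m <- object@memberIndices
  if (length(m) < 1) return("chunk must have at least one member")
  if (anyDuplicated(m)) return("member indices must be unique")
  if (!(object@anchorIndex %in% m)) return("members must contain the anchor")
  if (object@k < 1) return("k must be >= 1")
  if (length(m) > object@k) return("more members than k")
  TRUE
})

#' @param anchorIndex,anchorClass,memberIndices,k see slots.
#' @rdname Chunk-class
#' @export
Chunk <- function(anchorIndex, memberIndices, k, anchorClass = NA_integer_) {
  new("Chunk", anchorIndex = as.integer(anchorIndex),
      anchorClass = as.integer(anchorClass),
      memberIndices = as.integer(memberIndices), k = as.integer(k))
}

#' Per-class counts and fractions of a labelled point set
#'
#' @slot counts named numeric vector of per-class point counts (whole
#'   numbers; numeric storage so pooled training-set counts cannot overflow).
#' @slot scheme the \code{\linkS4class{ClassScheme}}.
#' @aliases classCounts classFractions
#' @export
setClass("ClassDistribution",
  representation(counts = "numeric", scheme = "ClassScheme"))

setValidity("ClassDistribution", function(object) {
  C <- length(object@scheme@classNames)
  if (length(object@counts) != C) return("counts must have one entry per class")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (any(abs(object@counts - round(object@counts)) > 1e-8))
    return("counts must be whole numbers")
  if (sum(object@counts) <= 0) return("distribution must contain at least one point")
  TRUE
})

#' @param counts per-class counts, in scheme order.
#' @param scheme a \code{\linkS4class{ClassScheme}}.
#' @rdname ClassDistribution-class
#' @export
ClassDistribution <- function(counts, scheme = defaultClassScheme()) {
  counts <- as.numeric(counts)
  names(counts) <- scheme@classNames
  new("ClassDistribution", counts = counts, scheme = scheme)
}

#' Per-class anchor allocation for one cloud
#'
#' @slot strategy \code{"class_independent"} (anchors proportional to the
#'   class distribution) or \code{"class_dependent"} (proportional to its
#'   inverse).
#' @slot anchorsPerClass named integer vector \code{a_c}, scheme order;
#'   \code{sum(a_c) == a}.
#' @slot k intended neighbourhood size (NA until chunks are extracted).
#' @slot scheme the \code{\linkS4class{ClassScheme}}.
#' @aliases anchorsPerClass
#' @export
setClass("SamplingPlan",
  representation(strategy = "character", anchorsPerClass = "integer",
                 k = "integer", scheme = "ClassScheme"))

setValidity("SamplingPlan", function(object) {
  if (!object@strategy %in% c("class_independent", "class_dependent"))
    return("unknown strategy")
  if (length(object@anchorsPerClass) != length(object@scheme@classNames))
    return("anchorsPerClass must have one entry per class")
  if (any(object@anchorsPerClass < 0)) return("anchor counts must be >= 0")
  TRUE
})

#' Point-wise confusion matrix (rows = true class, columns = predicted)
#'
#' @slot counts C x C integer-valued matrix of point counts.
#' @slot scheme the \code{\linkS4class{ClassScheme}}.
#' @aliases normalisedPercent
#' @export
setClass("ConfusionMatrix",
  representation(counts = "matrix", scheme = "ClassScheme"))

setValidity("ConfusionMatrix", function(object) {
  C <- length(object@scheme@classNames)
  if (!identical(dim(object@counts), c(C, C)))
    return("counts must be C x C")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' Segmentation quality report for one (merged) cloud
#'
#' Per-class intersection-over-union, precision and recall, plus the micro
#' average (pooled TP/FP/FN counts) and macro average (unweighted mean of the
#' defined per-class IoU values). Classes absent from both truth and
#' prediction have undefined metrics (NaN) and are excluded from the macro
#' mean.
#'
#' @slot iou,precision,recall named numeric per-class vectors (NaN where the
#'   denominator is 0).
#' @slot iouMicro,iouMacro single numerics.
#' @slot nPoints number of evaluated points.
#' @slot confusion the underlying \code{\linkS4class{ConfusionMatrix}}.
#' @export
setClass("MetricReport",
  representation(iou = "numeric", precision = "numeric", recall = "numeric",
                 iouMicro = "numeric", iouMacro = "numeric",
                 nPoints = "integer", confusion = "ConfusionMatrix"))

#' Audit record of majority-vote label fusion
#'
#' @slot votes n x C matrix of per-point vote counts.
#' @slot labels resolved 0-based labels (maximal vote count; ties broken
#'   uniformly at random).
#' @slot tie logical vector flagging points whose vote ended in a tie.
#' @export
setClass("VoteTally",
  representation(votes = "matrix", labels = "integer", tie = "logical"))

setValidity("VoteTally", function(object) {
  n <- nrow(object@votes)
  if (length(object@labels) != n || length(object@tie) != n)
    return("labels/tie must match vote matrix rows")
  TRUE
})

#' Box-plot style summary of the classes-per-chunk statistic
#'
#' @slot classesPerChunk integer, one distinct-class count per chunk.
#' @slot mean,lowerQuartile,upperQuartile numeric summaries.
#' @slot whiskerLow,whiskerHigh most extreme values within 1.5 x IQR of the
#'   quartiles.
#' @slot outliers values outside the whisker range.
#' @export
setClass("ChunkCompositionSummary",
  representation(classesPerChunk = "integer", mean = "numeric",
                 lowerQuartile = "numeric", upperQuartile = "numeric",
                 whiskerLow = "numeric", whiskerHigh = "numeric",
                 outliers = "integer"))
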