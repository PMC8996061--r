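# Imbalance diagnostics: class distributions, Shannon entropy (bits) and
# chunk-composition statistics.

#' Class distribution of a labelled cloud
#'
#' Counts the non-sentinel labels of a cloud (or a plain label vector) into a
#' \code{\linkS4class{ClassDistribution}}. Unlabelled points are never
#' counted.
#'
#' @param x a \code{\linkS4class{LabeledPointCloud}} or an integer vector of
#'   0-based labels (NA = unlabelled).
#' @param scheme used when \code{x} is a plain vector.
#' @return a \code{\linkS4class{ClassDistribution}}.
#' @examples
#' d <- ClassDistribution(c(789, 150, 27, 15, 5, 5, 5, 4))
#' classFractions(d)
#' shannonEntropy(d)
#' @export
classDistribution <- function(x, scheme = defaultClassScheme()) {
  if (is(x, "LabeledPointCloud")) {
    labels <- x@labels
    scheme <- x@scheme
  } else {
    labels <- as.integer(x)
  }
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0)
    stop("cannot form a class distribution: all labels are unlabelled")
  C <- nClasses(scheme)
  counts <- tabulate(labels + 1L, nbins = C)
  ClassDistribution(counts, scheme)
}

#' @rdname shannonEntropy
#' @export
setMethod("shannonEntropy", "ClassDistribution", function(x) {
  entropyBits(classFractions(x))
})

#' @rdname shannonEntropy
#' @export
setMethod("shannonEntropy", "numeric", function(x) {
  if (any(x < 0) || sum(x) <= 0)
    stop("class weights must be non-negative with a positive sum")
  entropyBits(x / sum(x))
})

entropyBits <- function(p) {
  p <- p[p > 0]  # 0 * log2(0) := 0
  -sum(p * log2(p))
}

#' Classes-per-chunk composition summary
#'
#' For each chunk, counts the number of distinct classes among its members'
#' labels, and summarises the statistic box-plot style: mean, quartiles,
#' whiskers at the most extreme values within 1.5 x IQR of the quartiles,
#' and outliers beyond the whiskers. Larger neighbourhoods pull in more of
#' the surrounding organs, so the mean rises with \code{k}.
#'
#' @param chunks list of \code{\linkS4class{Chunk}} objects.
#' @param cloud the labelled source cloud the chunks index into.
#' @return a \code{\linkS4class{ChunkCompositionSummary}}.
#' @export
chunkComposition <- function(chunks, cloud) {
  stopifnot(is(cloud, "LabeledPointCloud"), length(chunks) >= 1)
  n <- nPoints(cloud)
  labels <- cloud@labels
  stopIfUnlabelled(labels, "chunkComposition")
  cpc <- vapply(chunks, function(ch) {
    if (any(ch@memberIndices > n))
      stop("chunk references point beyond cloud '", cloud@cloudId, "'")
    length(unique(labels[ch@memberIndices]))
  }, integer(1))
  q <- unname(stats::quantile(cpc, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  inRange <- cpc >= lo & cpc <= hi
  new("ChunkCompositionSummary",
      classesPerChunk = cpc,
      mean = mean(cpc),
      lowerQuartile = q[1], upperQuartile = q[2],
      whiskerLow = if (any(inRange)) min(cpc[inRange]) else NA_real_,
      whiskerHigh = if (any(inRange)) max(cpc[inRange]) else NA_real_,
      outliers = cpc[!inRange])
}

#' Pooled class distribution of a training set
#'
#' Pools the labels of all chunk members over one or more clouds. A point
#' contributes once per chunk containing it, so overlapping chunks
#' double-count points -- exactly what the downstream segmenter sees as its
#' training distribution.
#'
#' @param chunks a list of \code{\linkS4class{Chunk}} objects (single cloud)
#'   or a list of such lists, parallel to \code{clouds}.
#' @param clouds a \code{\linkS4class{LabeledPointCloud}} or list thereof.
#' @return a \code{\linkS4class{ClassDistribution}}.
#' @export
trainingSetDistribution <- function(chunks, clouds) {
  if (is(clouds, "LabeledPointCloud")) {
    clouds <- list(clouds)
    chunks <- list(chunks)
  }
  stopifnot(length(chunks) == length(clouds))
  scheme <- classScheme(clouds[[1]])
  C <- nClasses(scheme)
  counts <- numeric(C)
  for (i in seq_along(clouds)) {
    labels <- clouds[[i]]@labels
    stopIfUnlabelled(labels, "trainingSetDistribution")
    n <- nPoints(clouds[[i]])
    for (ch in chunks[[i]]) {
      if (any(ch@memberIndices > n))
        stop("chunk references point beyond cloud '", clouds[[i]]@cloudId, "'")
      counts <- counts + tabulate(labels[ch@memberIndices] + 1L, nbins = C)
    }
  }
  if (sum(counts) == 0) stop("training set contains no labelled points")
  ClassDistribution(counts, scheme)
}
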