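# The pluggable segmenter contract (the slot a deep network such as
# PointNet++ occupies in production pipelines) plus a deliberately simple
# nearest-class-centroid baseline. The baseline exists to make sampling
# effects measurable at desk scale, not to rival a deep network: it is weak
# by design and documented as such.

#' Chunk views: the segmenter's input unit
#'
#' A view of a chunk is its members' six features -- x,y,z re-centred on the
#' anchor point (so the segmenter sees translation-invariant coordinates)
#' plus r,g,b -- together with the member indices and, when the source cloud
#' is labelled, the member labels.
#'
#' @param cloud the source \code{\linkS4class{LabeledPointCloud}}.
#' @param chunks list of \code{\linkS4class{Chunk}} objects.
#' @return list of views; each view is a list with \code{positions} (n x 3,
#'   anchor at the origin), \code{colours}, \code{labels} (may contain NA),
#'   \code{memberIndices}, \code{anchorIndex}.
#' @export
chunkViews <- function(cloud, chunks) {
  stopifnot(is(cloud, "LabeledPointCloud"))
  lapply(chunks, function(ch) {
    mi <- ch@memberIndices
    pos <- cloud@positions[mi, , drop = FALSE]
    pos <- sweep(pos, 2, cloud@positions[ch@anchorIndex, ], "-")
    list(positions = pos,
         colours = cloud@colours[mi, , drop = FALSE],
         labels = cloud@labels[mi],
         memberIndices = mi,
         anchorIndex = ch@anchorIndex)
  })
}

#' Segmenter contract and implementations
#'
#' A segmenter is any object with a \code{fitSegmenter(segmenter, views)}
#' method returning a trained model and a \code{predictSegmenter(model,
#' view)} method returning one 0-based label per chunk member. External
#' models (e.g. deep networks driven from another process) plug in by
#' subclassing \code{Segmenter} and providing the two methods.
#'
#' \code{baselineSegmenter()}: per-point feature vectors (height above the
#' chunk minimum, r, g, b, and covariance eigenvalue shape descriptors --
#' linearity, planarity, sphericity -- over the \code{kLocal} nearest
#' members within the chunk) feed a nearest-class-centroid rule on
#' standardised features. Fast, deterministic, and sensitive to the class
#' composition of its training chunks, which is exactly what is needed to
#' study sampling strategies.
#'
#' \code{oracleSegmenter()}: predicts the ground-truth labels of the view;
#' an upper bound used in tests.
#'
#' @param kLocal neighbourhood size of the local shape descriptors.
#' @name segmenter
#' @aliases Segmenter-class BaselineSegmenter-class OracleSegmenter-class
#'   BaselineModel-class fitSegmenter predictSegmenter
NULL

#' @export
setClass("Segmenter", representation("VIRTUAL"))

#' @export
setClass("BaselineSegmenter", contains = "Segmenter",
         representation(kLocal = "integer"))

#' @export
setClass("OracleSegmenter", contains = "Segmenter")

#' @rdname segmenter
#' @export
baselineSegmenter <- function(kLocal = 16L) {
  new("BaselineSegmenter", kLocal = as.integer(kLocal))
}

#' @rdname segmenter
#' @export
oracleSegmenter <- function() new("OracleSegmenter")

#' @export
setClass("BaselineModel",
  representation(centroids = "matrix", featureMean = "numeric",
                 featureSd = "numeric", classes = "integer",
                 kLocal = "integer"))

#' @export
setClass("OracleModel", representation(dummy = "logical"))

viewFeatures <- function(view, kLocal) {
  pos <- view$positions
  shape <- .localShapeFeatures(pos, as.integer(kLocal))
  cbind(height = pos[, 3] - min(pos[, 3]),
        r = as.numeric(view$colours[, 1]),
        g = as.numeric(view$colours[, 2]),
        b = as.numeric(view$colours[, 3]),
        shape)
}

#' @rdname segmenter
#' @param segmenter a \code{Segmenter} object.
#' @param views list of labelled chunk views (see \code{\link{chunkViews}}).
#' @param ... unused.
#' @export
setMethod("fitSegmenter", "BaselineSegmenter", function(segmenter, views, ...) {
  stopifnot(length(views) >= 1)
  feats <- do.call(rbind, lapply(views, viewFeatures, kLocal = segmenter@kLocal))
  labels <- unlist(lapply(views, `[[`, "labels"))
  keep <- !is.na(labels)
  feats <- feats[keep, , drop = FALSE]
  labels <- labels[keep]
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("baseline needs at least 2 classes among the training members")
  mu <- colMeans(feats)
  sdv <- apply(feats, 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  std <- sweep(sweep(feats, 2, mu), 2, sdv, "/")
  centroids <- t(vapply(classes, function(cl)
    colMeans(std[labels == cl, , drop = FALSE]), numeric(ncol(std))))
  rownames(centroids) <- classes
  new("BaselineModel", centroids = centroids, featureMean = mu,
      featureSd = sdv, classes = as.integer(classes),
      kLocal = segmenter@kLocal)
})

#' @rdname segmenter
#' @export
setMethod("fitSegmenter", "OracleSegmenter", function(segmenter, views, ...) {
  new("OracleModel", dummy = TRUE)
})

#' @rdname segmenter
#' @param model a trained model.
#' @param view one chunk view.
#' @export
setMethod("predictSegmenter", "BaselineModel", function(model, view, ...) {
  feats <- viewFeatures(view, model@kLocal)
  std <- sweep(sweep(feats, 2, model@featureMean), 2, model@featureSd, "/")
  # squared distance to every class centroid; nearest wins, ties to the
  # lower class index (row order of the centroid matrix)
  d2 <- outer(rowSums(std^2), rowSums(model@centroids^2), "+") -
    2 * std %*% t(model@centroids)
  model@classes[max.col(-d2, ties.method = "first")]
})

#' @rdname segmenter
#' @export
setMethod("predictSegmenter", "OracleModel", function(model, view, ...) {
  if (anyNA(view$labels)) stop("oracle segmenter needs labelled views")
  view$labels
})
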