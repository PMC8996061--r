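# Anchor allocation (proportional vs inverse-proportional), anchor sampling
# and k-NN chunk extraction -- the training-set construction machinery.

# Largest-remainder (Hamilton) integerisation of non-negative real quotas so
# that the integers sum to a exactly. Remainder ties break by vector order
# (i.e. ClassScheme order), making allocation fully deterministic.
largestRemainder <- function(raw, a) {
  stopifnot(all(raw >= 0), abs(sum(raw) - a) < 1e-6)
  base <- floor(raw)
  rem <- raw - base
  extra <- a - sum(base)
  if (extra > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(extra)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Allocate anchor points per class
#'
#' Two strategies split a total of \code{a} anchors over the classes of a
#' distribution:
#' \describe{
#'   \item{class-independent}{\code{a_c = (n_c / n) * a} -- anchors
#'     proportional to the class distribution, so the training set mirrors
#'     the (imbalanced) source data. The reference strategy.}
#'   \item{class-dependent}{\code{a_c = ((1 - n_c/n) / sum_i (1 - n_i/n)) * a}
#'     -- anchors proportional to the \emph{inverse} fraction (1 minus the
#'     class fraction, renormalised), focusing the training set on minority
#'     classes. The sum runs over classes present in the cloud; absent
#'     classes receive 0 anchors.}
#' }
#' Real-valued quotas are integerised by the largest-remainder rule (ties by
#' scheme order), so \code{sum(a_c) == a} exactly and the allocation is
#' deterministic. On a uniform distribution the two strategies coincide.
#'
#' @param dist a \code{\linkS4class{ClassDistribution}}.
#' @param a total number of anchors per cloud (>= 1).
#' @param strategy \code{"class_independent"} or \code{"class_dependent"}.
#' @return a \code{\linkS4class{SamplingPlan}}.
#' @examples
#' d <- ClassDistribution(c(27, 15, 789, 5, 5, 5, 5, 149))
#' anchorsPerClass(allocateAnchors(d, 100, "class_independent"))
#' anchorsPerClass(allocateAnchors(d, 100, "class_dependent"))
#' @export
allocateAnchors <- function(dist, a,
                            strategy = c("class_independent", "class_dependent")) {
  strategy <- match.arg(strategy)
  if (strategy == "class_independent") allocateAnchorsIndependent(dist, a)
  else allocateAnchorsDependent(dist, a)
}

#' @rdname allocateAnchors
#' @export
allocateAnchorsIndependent <- function(dist, a) {
  stopifnot(is(dist, "ClassDistribution"))
  a <- checkAnchorTotal(a)
  p <- classFractions(dist)
  ac <- largestRemainder(p * a, a)
  names(ac) <- classNames(dist@scheme)
  new("SamplingPlan", strategy = "class_independent", anchorsPerClass = ac,
      k = NA_integer_, scheme = dist@scheme)
}

#' @rdname allocateAnchors
#' @export
allocateAnchorsDependent <- function(dist, a) {
  stopifnot(is(dist, "ClassDistribution"))
  a <- checkAnchorTotal(a)
  p <- classFractions(dist)
  present <- classCounts(dist) > 0
  if (sum(present) < 2)
    stop("class-dependent allocation needs at least 2 present classes")
  inv <- ifelse(present, 1 - p, 0)
  raw <- inv / sum(inv) * a
  ac <- largestRemainder(raw, a)
  names(ac) <- classNames(dist@scheme)
  new("SamplingPlan", strategy = "class_dependent", anchorsPerClass = ac,
      k = NA_integer_, scheme = dist@scheme)
}

checkAnchorTotal <- function(a) {
  if (length(a) != 1 || is.na(a) || a < 1) stop("a must be a single integer >= 1")
  as.integer(a)
}

#' Sample anchor points according to a plan
#'
#' For each class \code{c}, draws \code{a_c} point indices uniformly without
#' replacement from the points of that class. If a plan demands more anchors
#' than a class has points, sampling falls back to with-replacement for that
#' class and a warning is issued (duplicate anchors then yield duplicate
#' chunks, the usual oversampling behaviour).
#'
#' @param cloud a labelled \code{\linkS4class{LabeledPointCloud}}.
#' @param plan a \code{\linkS4class{SamplingPlan}}.
#' @param seed optional integer; when given, draws come from a private seeded
#'   stream and the caller's RNG state is untouched.
#' @return data.frame with columns \code{index} (1-based point index) and
#'   \code{class} (0-based class of the anchor), in scheme order.
#' @export
sampleAnchorPoints <- function(cloud, plan, seed = NULL) {
  stopifnot(is(cloud, "LabeledPointCloud"), is(plan, "SamplingPlan"))
  labels <- cloud@labels
  ac <- plan@anchorsPerClass
  idx <- integer(0)
  cls <- integer(0)
  withSeed(seed, {
    for (ci in seq_along(ac)) {
      if (ac[ci] == 0L) next
      pool <- which(labels == ci - 1L)
      if (length(pool) == 0)
        stop("plan demands anchors for class '", names(ac)[ci],
             "' which is absent from cloud '", cloud@cloudId, "'")
      if (ac[ci] > length(pool)) {
        warning(sprintf(
          "class '%s': %d anchors requested from %d points; sampling with replacement",
          names(ac)[ci], ac[ci], length(pool)))
        draw <- pool[sample.int(length(pool), ac[ci], replace = TRUE)]
      } else {
        draw <- pool[sample.int(length(pool), ac[ci], replace = FALSE)]
      }
      idx <- c(idx, draw)
      cls <- c(cls, rep(ci - 1L, ac[ci]))
    }
  })
  data.frame(index = idx, class = cls)
}

#' Extract the k-nearest-neighbour chunk around an anchor
#'
#' Members are the \code{min(k, n)} points nearest to the anchor by Euclidean
#' distance on x,y,z only (colour is a feature, not geometry), anchor
#' included at distance 0, ordered by distance with exact ties broken by
#' ascending point index. The search always runs over the entire cloud, so a
#' chunk may contain points of any class.
#'
#' @param cloud a \code{\linkS4class{LabeledPointCloud}}.
#' @param anchorIndex 1-based anchor point index.
#' @param k neighbourhood size (>= 1); truncated to n when k > n.
#' @return a \code{\linkS4class{Chunk}}.
#' @export
extractChunk <- function(cloud, anchorIndex, k) {
  stopifnot(is(cloud, "LabeledPointCloud"))
  if (k < 1) stop("k must be >= 1")
  n <- nPoints(cloud)
  if (anchorIndex < 1 || anchorIndex > n) stop("anchor index out of range")
  members <- .knnFromPoint(cloud@positions, as.integer(anchorIndex), as.integer(k))
  Chunk(anchorIndex = anchorIndex, memberIndices = members, k = k,
        anchorClass = cloud@labels[anchorIndex])
}

#' Build a training set of chunks over one or more clouds
#'
#' For each cloud: class distribution -> anchor allocation under the chosen
#' strategy -> anchor sampling -> k-NN chunk extraction. Returns the chunks
#' per cloud together with the pooled training-set distribution and its
#' entropy, the quantities compared between the class-independent and
#' class-dependent strategies.
#'
#' @param clouds a labelled cloud or list of labelled clouds.
#' @param strategy \code{"class_independent"} or \code{"class_dependent"}.
#' @param a anchors per cloud (default 100).
#' @param k neighbourhood size (default 4096).
#' @param seed integer master seed; per-cloud substreams are derived from it,
#'   so adding a cloud does not perturb the draws of the others.
#' @param manifestDir optional directory; when given, one JSON chunk manifest
#'   is written per cloud.
#' @return list with elements \code{chunks} (list per cloud), \code{plans}
#'   (list of \code{\linkS4class{SamplingPlan}}), \code{distribution} (pooled
#'   \code{\linkS4class{ClassDistribution}}), \code{entropy} (bits),
#'   \code{strategy}, \code{a}, \code{k}.
#' @examples
#' pl <- generatePlant(plantParams(nPoints = 2000, seed = 1))
#' ts <- buildTrainingSet(pl, "class_dependent", a = 10, k = 64, seed = 1)
#' ts$entropy
#' @export
buildTrainingSet <- function(clouds, strategy = c("class_independent",
                                                  "class_dependent"),
                             a = 100, k = 4096, seed = NULL,
                             manifestDir = NULL) {
  strategy <- match.arg(strategy)
  if (is(clouds, "LabeledPointCloud")) clouds <- list(clouds)
  allChunks <- vector("list", length(clouds))
  plans <- vector("list", length(clouds))
  for (i in seq_along(clouds)) {
    cloud <- clouds[[i]]
    dist <- classDistribution(cloud)
    plan <- allocateAnchors(dist, a, strategy)
    plan@k <- as.integer(k)
    anchors <- sampleAnchorPoints(cloud, plan,
                                  seed = if (is.null(seed)) NULL
                                         else subSeed(seed, "anchors", i))
    chunks <- lapply(seq_len(nrow(anchors)), function(j)
      extractChunk(cloud, anchors$index[j], k))
    allChunks[[i]] <- chunks
    plans[[i]] <- plan
    if (!is.null(manifestDir)) {
      if (!dir.exists(manifestDir)) dir.create(manifestDir, recursive = TRUE)
      writeChunkSet(chunks, cloud@cloudId,
                    file.path(manifestDir, paste0(cloud@cloudId, "_chunks.json")),
                    nPoints = nPoints(cloud))
    }
  }
  dist <- trainingSetDistribution(allChunks, clouds)
  list(chunks = allChunks, plans = plans, distribution = dist,
       entropy = shannonEntropy(dist), strategy = strategy,
       a = as.integer(a), k = as.integer(k))
}
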