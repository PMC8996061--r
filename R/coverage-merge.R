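# Test-time machinery: chunk a cloud until every point is covered, and fuse
# overlapping per-chunk predictions by majority vote.

#' Cover a cloud with chunks
#'
#' Iteratively selects an anchor uniformly at random from the points not yet
#' contained in any chunk, extracts its k-NN chunk over the \emph{entire}
#' cloud (preserving local structure and density), and repeats until every
#' point belongs to at least one chunk. Anchor selection ignores labels:
#' at deployment time test clouds are unlabelled.
#'
#' @param cloud a \code{\linkS4class{LabeledPointCloud}} (labels not used).
#' @param k neighbourhood size.
#' @param seed optional integer seed for the anchor draws.
#' @param batchSize anchors drawn per iteration from the uncovered set
#'   (default 1, the strict iterative scheme; larger values speed up very
#'   large clouds at the cost of slightly more chunks).
#' @return list of \code{\linkS4class{Chunk}} objects whose member sets
#'   jointly cover all n points. Terminates in at most n iterations since
#'   every chunk covers its own anchor.
#' @export
coverCloud <- function(cloud, k, seed = NULL, batchSize = 1L) {
  stopifnot(is(cloud, "LabeledPointCloud"))
  if (k < 1) stop("k must be >= 1")
  n <- nPoints(cloud)
  covered <- logical(n)
  chunks <- list()
  withSeed(seed, {
    while (!all(covered)) {
      uncovered <- which(!covered)
      nb <- min(batchSize, length(uncovered))
      anchors <- if (length(uncovered) == 1L) uncovered
                 else uncovered[sample.int(length(uncovered), nb)]
      for (anc in anchors) {
        ch <- extractChunk(cloud, anc, k)
        covered[ch@memberIndices] <- TRUE
        chunks[[length(chunks) + 1L]] <- ch
      }
    }
  })
  chunks
}

#' Merge per-chunk predictions by majority vote
#'
#' Each point receives one vote per chunk prediction that contains it; the
#' resolved label is the class with the maximal vote count. Ties are broken
#' uniformly at random among the tied classes using the seeded stream, so a
#' merge is deterministic given the seed and, in the absence of ties,
#' seed-independent.
#'
#' @param n number of points of the cloud being reassembled.
#' @param predictions list of chunk predictions, each a list with elements
#'   \code{memberIndices} (1-based) and \code{labels} (0-based, same length).
#' @param scheme the \code{\linkS4class{ClassScheme}}.
#' @param seed optional integer seed for tie-breaking.
#' @return a \code{\linkS4class{VoteTally}}; resolved labels via
#'   \code{pointLabels}-style slot \code{labels}.
#' @export
mergePredictions <- function(n, predictions, scheme = defaultClassScheme(),
                             seed = NULL) {
  C <- nClasses(scheme)
  votes <- matrix(0L, nrow = n, ncol = C,
                  dimnames = list(NULL, classNames(scheme)))
  for (pr in predictions) {
    mi <- pr$memberIndices
    lb <- pr$labels
    if (length(mi) != length(lb))
      stop("prediction member/label lengths differ")
    if (any(mi < 1 | mi > n)) stop("prediction references point outside 1..n")
    if (any(lb < 0 | lb >= C)) stop("predicted label outside 0..C-1")
    ij <- cbind(mi, lb + 1L)
    # a chunk has unique members, so no within-chunk double vote is possible
    votes[ij] <- votes[ij] + 1L
  }
  uncovered <- which(rowSums(votes) == 0L)
  if (length(uncovered))
    stop("points without any prediction: ",
         paste(utils::head(uncovered, 10L), collapse = ", "),
         if (length(uncovered) > 10L) " ..." else "")
  maxVote <- do.call(pmax, as.data.frame(votes))
  isMax <- votes == maxVote
  nMax <- rowSums(isMax)
  labels <- max.col(votes, ties.method = "first") - 1L
  tie <- nMax > 1L
  if (any(tie)) {
    withSeed(seed, {
      for (i in which(tie)) {
        cand <- which(isMax[i, ])
        labels[i] <- cand[sample.int(length(cand), 1L)] - 1L
      }
    })
  }
  new("VoteTally", votes = votes, labels = as.integer(labels), tie = tie)
}
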