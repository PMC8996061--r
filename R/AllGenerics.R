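#' @rdname LabeledPointCloud-class
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname ClassScheme-class
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname ClassScheme-class
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' @rdname LabeledPointCloud-class
#' @export
setGeneric("classScheme", function(x) standardGeneric("classScheme"))

#' @rdname ClassDistribution-class
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname ClassDistribution-class
#' @export
setGeneric("classFractions", function(x) standardGeneric("classFractions"))

#' Shannon entropy of a class distribution, in bits
#'
#' \code{h = -sum(p_c * log2(p_c))} with the convention \code{0 * log2(0) = 0}.
#' For \code{C} classes the entropy lies in \code{[0, log2(C)]}: 0 for a
#' single-class dataset, \code{log2(C)} when all classes are equally present.
#' The entropy of the class fractions is the package's measure of class
#' (im)balance in a dataset or training set.
#'
#' @param x a \code{\linkS4class{ClassDistribution}}, or a numeric vector of
#'   non-negative class weights (counts or fractions; normalised internally).
#' @return entropy in bits (full precision; round only for display).
#' @examples
#' shannonEntropy(rep(1, 8))          # balanced: log2(8) = 3 bits
#' shannonEntropy(c(1, 0, 0, 0))      # degenerate: 0 bits
#' @export
setGeneric("shannonEntropy", function(x) standardGeneric("shannonEntropy"))

#' @rdname evaluation
#' @export
setGeneric("iouPerClass", function(x) standardGeneric("iouPerClass"))

#' @rdname evaluation
#' @export
setGeneric("iouMicro", function(x) standardGeneric("iouMicro"))

#' @rdname evaluation
#' @export
setGeneric("iouMacro", function(x) standardGeneric("iouMacro"))

#' @rdname evaluation
#' @export
setGeneric("precisionRecall", function(x) standardGeneric("precisionRecall"))

#' @rdname ConfusionMatrix-class
#' @export
setGeneric("normalisedPercent", function(x) standardGeneric("normalisedPercent"))

#' @rdname diffNormalised
#' @export
setGeneric("diffNormalised", function(a, b) standardGeneric("diffNormalised"))

#' @rdname Chunk-class
#' @export
setGeneric("memberIndices", function(x) standardGeneric("memberIndices"))

#' @rdname Chunk-class
#' @export
setGeneric("anchorIndex", function(x) standardGeneric("anchorIndex"))

#' @rdname Chunk-class
#' @export
setGeneric("anchorClass", function(x) standardGeneric("anchorClass"))

#' @rdname SamplingPlan-class
#' @export
setGeneric("anchorsPerClass", function(x) standardGeneric("anchorsPerClass"))

#' @rdname segmenter
#' @export
setGeneric("fitSegmenter", function(segmenter, views, ...) standardGeneric("fitSegmenter"))

#' @rdname segmenter
#' @export
setGeneric("predictSegmenter", function(model, view, ...) standardGeneric("predictSegmenter"))
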