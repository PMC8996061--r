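# Small internal helpers: seeded evaluation, deterministic sub-seeds and
# report rounding.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL uses the current stream (and advances it).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic sub-seed for (stage, index) so adding a cloud or a stage does
# not perturb the draws of the others. Kept inside 32-bit integer range.
subSeed <- function(seed, stage, index = 0L) {
  h <- (as.double(seed) * 48271 + match(stage, c("plant", "anchors", "cover",
                                                 "merge", "fit", "split",
                                                 "experiment")) * 9631 +
        as.double(index) * 127) %% 2147483629
  as.integer(h) + 1L
}

# Round half away from zero (reports match printed tables; base round() is
# half-to-even, which e.g. turns a 92.5% diagonal into recall 0.92).
#' Round half away from zero
#'
#' Display rounding used in reports: halves round away from zero, so a recall
#' of 0.925 prints as 0.93 (base \code{round} would give 0.92).
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# 0-based labels <-> factor with scheme names
labelFactor <- function(labels, scheme) {
  factor(classNames(scheme)[labels + 1L], levels = classNames(scheme))
}

stopIfUnlabelled <- function(labels, what = "operation") {
  if (anyNA(labels))
    stop(sprintf("%s requires labelled points (found unlabelled sentinel)", what))
}
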