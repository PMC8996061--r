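# Independent brute-force oracles and small fixture builders. The oracles
# deliberately avoid the package's own code paths.

# Largest-remainder apportionment by exhaustive search: floors plus the
# subset of classes (of the required size) whose remainders have maximal
# sum. Returns all optimal allocations (ties yield several).
oracleLargestRemainder <- function(raw, a) {
  base <- floor(raw)
  rem <- raw - base
  extra <- a - sum(base)
  if (extra == 0) return(list(as.integer(base)))
  combos <- utils::combn(length(raw), extra, simplify = FALSE)
  sums <- vapply(combos, function(ix) sum(rem[ix]), numeric(1))
  best <- combos[abs(sums - max(sums)) < 1e-12]
  lapply(best, function(ix) {
    out <- base
    out[ix] <- out[ix] + 1
    as.integer(out)
  })
}

# Is allocation x one of the optimal allocations in the oracle's set?
inAllocSet <- function(x, set) {
  any(vapply(set, identical, logical(1), as.integer(unname(x))))
}

# k nearest neighbours by full distance sort in plain R, ties by index.
oracleKnn <- function(positions, anchor, k) {
  d2 <- colSums((t(positions) - positions[anchor, ])^2)
  order(d2, seq_along(d2))[seq_len(min(k, nrow(positions)))]
}

# Per-point TP/FP/FN tally by explicit loop.
oracleTally <- function(trueLabels, predLabels, C) {
  tp <- fp <- fn <- numeric(C)
  for (i in seq_along(trueLabels)) {
    t_ <- trueLabels[i] + 1L
    p_ <- predLabels[i] + 1L
    if (t_ == p_) tp[t_] <- tp[t_] + 1
    else {
      fp[p_] <- fp[p_] + 1
      fn[t_] <- fn[t_] + 1
    }
  }
  list(tp = tp, fp = fp, fn = fn)
}

# Per-class IoU straight from label vectors as set intersection over union.
oracleIouFromLabels <- function(trueLabels, predLabels, C) {
  vapply(seq_len(C) - 1L, function(cl) {
    t_ <- trueLabels == cl
    p_ <- predLabels == cl
    u <- sum(t_ | p_)
    if (u == 0) NaN else sum(t_ & p_) / u
  }, numeric(1))
}

# Random labelled cloud on a uniform cube (no structure; for geometry tests).
randomCloud <- function(n, seed, C = 8, side = 100) {
  set.seed(seed)
  LabeledPointCloud(matrix(runif(3 * n, 0, side), ncol = 3),
                    matrix(sample(0:255, 3 * n, replace = TRUE), ncol = 3),
                    sample(0:(C - 1), n, replace = TRUE),
                    cloudId = sprintf("random_%d", seed))
}

# The heavily imbalanced reference fractions (printed profile: leaf 78.9%,
# non-plant 15.0%, stem 2.7%, petiole 1.5%, rest split evenly).
referenceFractions <- function() {
  c(stem = 0.027, petiole = 0.015, leaf = 0.789,
    growing_point = 0.019 / 4, node = 0.019 / 4, ovary = 0.019 / 4,
    tendril = 0.019 / 4, non_plant = 0.150)
}
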