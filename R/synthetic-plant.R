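# Procedural generator of labelled cucumber-like point clouds. The geometry
# is stylised: what the sampling and evaluation machinery needs is exact
# control over class fractions, locally separable organ geometry/colour and
# realistic adjacency (nodes and ovaries sit on the stem), not botanical
# accuracy.

#' Parameters of the synthetic plant generator
#'
#' Defaults emulate a single trellised cucumber plant as scanned by a
#' laser-triangulation system: a vertical stem with nodes at the internode
#' junctions, petioles branching to planar elliptical leaf blades, curled
#' tendrils, an apical growing point, ovaries at a subset of nodes, and a
#' non-plant background (pot disc, gutter plane, vertical support wire).
#' The default class fractions reproduce the strongly imbalanced profile of
#' a real labelled cucumber dataset: leaf 78.9%, non-plant 15.0%, stem 2.7%,
#' petiole 1.5% and 0.475% for each of growing point, node, ovary and
#' tendril (entropy about 1.06 bits).
#'
#' @slot nPoints target total number of points (>= 8 per class).
#' @slot targetFractions named per-class fractions summing to 1 (scheme
#'   order); realised counts are integerised by largest remainder, so the
#'   achieved fractions match the targets to within 1/nPoints.
#' @slot nLeavesRange inclusive range the number of leaves is drawn from.
#' @slot plantHeightRange range of plant heights, mm.
#' @slot colourNoiseSd s.d. of Gaussian RGB noise (clipped to 0..255).
#' @slot positionNoiseSd s.d. of isotropic positional jitter, mm.
#' @slot seed integer seed; clouds are deterministic given the seed.
#' @slot scheme the \code{\linkS4class{ClassScheme}}.
#' @export
setClass("PlantParams",
  representation(nPoints = "integer", targetFractions = "numeric",
                 nLeavesRange = "integer", plantHeightRange = "numeric",
                 colourNoiseSd = "numeric", positionNoiseSd = "numeric",
                 seed = "integer", scheme = "ClassScheme"))

setValidity("PlantParams", function(object) {
  C <- nClasses(object@scheme)
  f <- object@targetFractions
  if (length(f) != C) return("one target fraction per class required")
  if (any(f <= 0) || any(f >= 1)) return("fractions must lie in (0, 1)")
  if (abs(sum(f) - 1) > 1e-9) return("fractions must sum to 1")
  if (object@nPoints < 8L * C) return("nPoints must be at least 8 per class")
  if (any(f * object@nPoints < 1))
    return("infeasible fractions: a class would receive less than one point")
  TRUE
})

#' @param nPoints,targetFractions,nLeavesRange,plantHeightRange see slots.
#' @param colourNoiseSd,positionNoiseSd,seed,scheme see slots.
#' @rdname PlantParams-class
#' @export
plantParams <- function(nPoints = 50000,
                        targetFractions = c(stem = 0.027, petiole = 0.015,
                                            leaf = 0.789, growing_point = 0.00475,
                                            node = 0.00475, ovary = 0.00475,
                                            tendril = 0.00475, non_plant = 0.150),
                        nLeavesRange = c(8L, 12L),
                        plantHeightRange = c(760, 1950),
                        colourNoiseSd = 12, positionNoiseSd = 0.8,
                        seed = 1L, scheme = defaultClassScheme()) {
  new("PlantParams", nPoints = as.integer(nPoints),
      targetFractions = unname(targetFractions),
      nLeavesRange = as.integer(nLeavesRange),
      plantHeightRange = as.numeric(plantHeightRange),
      colourNoiseSd = colourNoiseSd, positionNoiseSd = positionNoiseSd,
      seed = as.integer(seed), scheme = scheme)
}

# organ-typical RGB means; stem / petiole / node deliberately close so the
# node<->stem confusability of real data is reproduced
ORGAN_COLOURS <- rbind(
  stem          = c(100, 160, 90),
  petiole       = c(95, 155, 85),
  leaf          = c(55, 130, 50),
  growing_point = c(120, 185, 100),
  node          = c(105, 158, 92),
  ovary         = c(190, 200, 90),
  tendril       = c(130, 175, 95),
  non_plant     = c(105, 100, 98))

#' Generate one labelled synthetic plant cloud
#'
#' Deterministic given \code{params@seed}. Organ labels are assigned by the
#' generating surface, so there are no mislabelled points by construction;
#' per-class point counts are solved by largest remainder, so achieved
#' fractions equal the targets to within 1/nPoints.
#'
#' @param params a \code{\linkS4class{PlantParams}} object.
#' @param cloudId identifier for the generated cloud.
#' @return a \code{\linkS4class{LabeledPointCloud}}.
#' @examples
#' pl <- generatePlant(plantParams(nPoints = 5000, seed = 42))
#' classFractions(classDistribution(pl))
#' @export
generatePlant <- function(params = plantParams(), cloudId = "synthetic_plant") {
  stopifnot(is(params, "PlantParams"))
  validObject(params)
  scheme <- params@scheme
  counts <- largestRemainder(params@targetFractions * params@nPoints,
                             params@nPoints)
  names(counts) <- classNames(scheme)
  withSeed(params@seed, {
    H <- stats::runif(1, params@plantHeightRange[1], params@plantHeightRange[2])
    nL <- sample(seq(params@nLeavesRange[1], params@nLeavesRange[2]), 1)
    geom <- plantGeometry(H, nL)
    parts <- list(
      stem          = sampleStem(counts["stem"], geom),
      petiole       = samplePetioles(counts["petiole"], geom),
      leaf          = sampleLeaves(counts["leaf"], geom),
      growing_point = sampleGrowingPoint(counts["growing_point"], geom),
      node          = sampleNodes(counts["node"], geom),
      ovary         = sampleOvaries(counts["ovary"], geom),
      tendril       = sampleTendrils(counts["tendril"], geom),
      non_plant     = sampleNonPlant(counts["non_plant"], geom))
    pos <- do.call(rbind, parts)
    labels <- rep(seq_along(parts) - 1L, times = vapply(parts, nrow, integer(1)))
    n <- nrow(pos)
    pos <- pos + matrix(stats::rnorm(3 * n, sd = params@positionNoiseSd),
                        ncol = 3)
    col <- ORGAN_COLOURS[labels + 1L, , drop = FALSE] +
      matrix(stats::rnorm(3 * n, sd = params@colourNoiseSd), ncol = 3)
    col <- matrix(as.integer(pmin(255, pmax(0, round(col)))), ncol = 3)
    LabeledPointCloud(pos, col, labels, cloudId = cloudId, scheme = scheme)
  })
}

# Shared skeleton: stem centreline, node positions, petiole/leaf frames.
plantGeometry <- function(H, nL) {
  stemCentre <- function(z) {
    cbind(15 * sin(z / H * 2 * pi * 0.7), 12 * sin(z / H * 2 * pi * 0.5 + 1), z)
  }
  nodeZ <- H * seq_len(nL) / (nL + 1)
  nodeCentres <- stemCentre(nodeZ)
  phi <- (seq_len(nL) - 1) * 137.5 * pi / 180  # phyllotactic azimuths
  outDir <- cbind(cos(phi), sin(phi), 0)
  petioleLen <- 80 + 40 * stats::runif(nL)
  # petioles leave the node pointing slightly downwards
  petioleDir <- outDir
  petioleDir[, 3] <- -0.25
  petioleDir <- petioleDir / sqrt(rowSums(petioleDir^2))
  leafAttach <- nodeCentres + petioleDir * petioleLen
  list(H = H, nL = nL, stemCentre = stemCentre, nodeZ = nodeZ,
       nodeCentres = nodeCentres, outDir = outDir, petioleDir = petioleDir,
       petioleLen = petioleLen, leafAttach = leafAttach,
       stemRadius = 5, nodeRadius = 9)
}

tubePoints <- function(n, start, dir, len, radius) {
  # points on a cylinder of given axis; dir must be unit length
  t <- stats::runif(n)
  axis <- start[rep(1, n), , drop = FALSE] + t * len * dir[rep(1, n), , drop = FALSE]
  # orthonormal frame around dir
  ref <- if (abs(dir[1, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- pracmaCross(dir[1, ], ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracmaCross(dir[1, ], e1)
  th <- stats::runif(n, 0, 2 * pi)
  axis + radius * (cos(th) %o% e1 + sin(th) %o% e2)
}

pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

sampleStem <- function(n, g) {
  z <- stats::runif(n, 0, g$H)
  centre <- g$stemCentre(z)
  th <- stats::runif(n, 0, 2 * pi)
  centre + g$stemRadius * cbind(cos(th), sin(th), 0)
}

sampleNodes <- function(n, g) {
  which_ <- sample.int(g$nL, n, replace = TRUE)
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- g$nodeRadius * stats::runif(n, 0.7, 1)^(1 / 3)
  g$nodeCentres[which_, , drop = FALSE] + u * r
}

samplePetioles <- function(n, g) {
  which_ <- sample.int(g$nL, n, replace = TRUE)
  out <- matrix(0, n, 3)
  for (i in unique(which_)) {
    sel <- which_ == i
    out[sel, ] <- tubePoints(sum(sel), g$nodeCentres[i, , drop = FALSE],
                             g$petioleDir[i, , drop = FALSE],
                             g$petioleLen[i], 3)
  }
  out
}

sampleLeaves <- function(n, g) {
  which_ <- sample.int(g$nL, n, replace = TRUE)
  a <- 110; b <- 85  # blade semi-axes, mm
  # uniform on the unit disc, then stretched to the ellipse
  r <- sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  u <- r * cos(th); v <- r * sin(th)
  out <- matrix(0, n, 3)
  for (i in unique(which_)) {
    sel <- which_ == i
    e1 <- g$outDir[i, ]  # blade long axis continues the petiole direction
    e2 <- pracmaCross(c(0, 0, 1), e1); e2 <- e2 / sqrt(sum(e2^2))
    centre <- g$leafAttach[i, ] + e1 * a * 0.8
    pt <- sweep(outer(u[sel] * a, e1) + outer(v[sel] * b, e2), 2,
                centre, "+")
    droop <- 25 * (u[sel]^2 + v[sel]^2)  # blades curve downwards at the rim
    pt[, 3] <- pt[, 3] - droop
    out[sel, ] <- pt
  }
  out
}

sampleGrowingPoint <- function(n, g) {
  apex <- g$stemCentre(g$H)
  apex[rep(1, n), , drop = FALSE] + matrix(stats::rnorm(3 * n, sd = 8), ncol = 3)
}

sampleOvaries <- function(n, g) {
  hosts <- seq_len(max(1L, ceiling(g$nL / 3)))  # ovaries at the lowest nodes
  which_ <- hosts[sample.int(length(hosts), n, replace = TRUE)]
  centres <- g$nodeCentres[which_, , drop = FALSE] +
    g$outDir[which_, , drop = FALSE] * 12
  centres[, 3] <- centres[, 3] - 18
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- stats::runif(n)^(1 / 3)
  centres + u * r * matrix(rep(c(6, 6, 14), each = n), ncol = 3)
}

sampleTendrils <- function(n, g) {
  hosts <- which(seq_len(g$nL) %% 2 == 0)
  if (length(hosts) == 0) hosts <- 1L
  which_ <- hosts[sample.int(length(hosts), n, replace = TRUE)]
  t <- stats::runif(n)
  base <- g$nodeCentres[which_, , drop = FALSE]
  outd <- g$outDir[which_, , drop = FALSE]
  # curled helix leaving the node
  base + outd * (60 * t) +
    cbind(8 * cos(6 * pi * t), 8 * sin(6 * pi * t), 30 * t)
}

sampleNonPlant <- function(n, g) {
  nPot <- round(0.30 * n); nWire <- round(0.15 * n)
  nGutter <- n - nPot - nWire
  # pot: disc of radius 80 at the base
  r <- 80 * sqrt(stats::runif(nPot)); th <- stats::runif(nPot, 0, 2 * pi)
  pot <- cbind(r * cos(th), r * sin(th), stats::runif(nPot, -15, 0))
  # gutter: long plane below the pot
  gutter <- cbind(stats::runif(nGutter, -450, 450),
                  stats::runif(nGutter, -120, 120),
                  -25 + stats::rnorm(nGutter, sd = 2))
  # support wire: thin vertical line next to the stem
  wz <- stats::runif(nWire, 0, g$H * 1.02)
  wire <- cbind(30 + stats::rnorm(nWire, sd = 1),
                stats::rnorm(nWire, sd = 1), wz)
  rbind(pot, gutter, wire)
}

#' Generate a dataset of synthetic plants
#'
#' Generates \code{nPlants} independent plants with per-plant seeds derived
#' deterministically from \code{masterSeed} (regeneration with the same
#' master seed is byte-identical), optionally writes each cloud as ASCII PLY
#' plus a JSON dataset manifest, and optionally splits the plants into
#' train/validation/test sets by plant identity, so no plant leaks across
#' sets.
#'
#' @param nPlants number of plants.
#' @param params a \code{\linkS4class{PlantParams}} template (its seed slot
#'   is overridden per plant).
#' @param masterSeed integer master seed.
#' @param dir optional output directory for PLY files and manifest.
#' @param split optional named integer vector, e.g.
#'   \code{c(train = 8, validation = 2, test = 2)}; must sum to nPlants.
#' @return list with \code{clouds} (list of
#'   \code{\linkS4class{LabeledPointCloud}}), \code{split} (named list of
#'   cloud ids or NULL), and \code{dir}.
#' @export
generateDataset <- function(nPlants, params = plantParams(), masterSeed = 1L,
                            dir = NULL, split = NULL) {
  stopifnot(nPlants >= 1)
  ids <- sprintf("plant_%02d", seq_len(nPlants))
  clouds <- vector("list", nPlants)
  for (i in seq_len(nPlants)) {
    p <- params
    p@seed <- subSeed(masterSeed, "plant", i)
    clouds[[i]] <- generatePlant(p, cloudId = ids[i])
  }
  names(clouds) <- ids
  splitIds <- NULL
  if (!is.null(split)) {
    if (sum(split) != nPlants) stop("split must sum to nPlants")
    assign_ <- withSeed(subSeed(masterSeed, "split"), sample(rep(names(split), split)))
    splitIds <- split(ids, factor(assign_, levels = names(split)))
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(nPlants))
      writeCloud(clouds[[i]], file.path(dir, paste0(ids[i], ".ply")))
    jsonlite::write_json(
      list(n_plants = nPlants, master_seed = masterSeed,
           cloud_ids = ids, split = splitIds,
           n_points = params@nPoints),
      file.path(dir, "dataset_manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(clouds = clouds, split = splitIds, dir = dir)
}
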