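---
title: "Class-dependent chunk sampling for plant point-cloud segmentation: methods and design"
author: "phytochunk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-dependent chunk sampling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytochunk)
```

## The problem

Point clouds of crop plants are extremely class-imbalanced. In a labelled
cucumber dataset the leaf contributes roughly 78.9% of the points and the
non-plant background (pot, gutter, support wire) another 15.0%, while the
organs a breeder actually wants to measure — nodes, ovaries, tendrils, the
growing point — each contribute well under 1%. Chunk-based deep segmenters
(a point cloud is too large to process at once, so training samples are
fixed-size neighbourhoods, "chunks") inherit this imbalance from the data,
and their per-class accuracy on the minority organs collapses.

`phytochunk` implements a sampling remedy that acts on how the chunks are
*created*, not on the network or its loss. A chunk is an anchor point plus
its $k$ nearest neighbours (Euclidean distance on $x,y,z$ only; the search
runs over the whole cloud). Per cloud, $a$ anchors are split over the $C$
classes in one of two ways:

* **class-independent** (the reference): $a_c = \frac{n_c}{n}\,a$ — the
  training set mirrors the source distribution;
* **class-dependent** (the method): $a_c = \frac{1 - n_c/n}
  {\sum_{i=1}^{C}\left(1 - n_i/n\right)}\,a$ — anchors are allocated
  proportionally to the *inverse* class fraction, focusing the training
  set on minority organs.

Imbalance is quantified by the Shannon entropy of the class fractions,
$h = -\sum_c p_c \log_2 p_c$ (bits), with $0\log 0 := 0$: $h = 0$ for a
single-class set, $h = \log_2 C$ ($= 3$ for $C = 8$) for a perfectly
balanced one. The printed cucumber distribution has $h \approx 1.06$
(reported as 1.1 bits).

```{r entropy}
ref <- cucumberReferenceTables()
shannonEntropy(ref$fractions)
anchorsPerClass(allocateAnchors(ClassDistribution(ref$fractions * 2e5),
                                100, "class_dependent"))
```

## Numerical choices

**Integerisation of the anchor quotas.** The allocation formulas produce
real quotas; how they become integers summing exactly to $a$ is not part of
the formulas. We use largest-remainder (Hamilton) rounding — floors plus
one extra anchor to the largest fractional remainders — with remainder ties
broken by class order. This guarantees $\sum_c a_c = a$ exactly, is
deterministic, and coincides with naive rounding whenever that already
sums to $a$. Classes absent from a cloud are excluded from the
class-dependent denominator and receive $a_c = 0$ (an anchor "randomly
selected from the points of that class" is undefined for an empty class).
If a plan demands more anchors than a class has points, sampling falls back
to with-replacement for that class with a warning; duplicated anchors then
yield duplicated chunks, the usual oversampling behaviour.

**k-NN ties and truncation.** Exact distance ties are broken by ascending
point index, making chunk membership platform-deterministic; $k > n$
truncates to $n$. The tie rule matters in degenerate geometry (collinear
grids) and in tests, not in practice.

**Randomness.** Every stochastic stage (anchor draws, coverage anchors,
vote tie-breaks, plant generation) accepts a seed; a master seed spawns
per-cloud, per-stage substreams deterministically, so adding a cloud to a
dataset does not perturb the draws of the others, and every experiment
writes its seeds into a manifest sufficient to reproduce it bit-exactly.

**Display rounding.** Metrics are kept at full precision and rounded only
for display (2 decimals for metrics, 1 for percentages), using
half-away-from-zero rounding: the reference tables print a recall of 0.93
for a 92.5% diagonal, which half-to-even rounding would render 0.92.

## Test-time coverage and vote merging

At prediction time the class distribution is unknown, so test clouds are
chunked by *coverage*: anchors are drawn uniformly from the not-yet-covered
points, one per iteration, each expanded to its $k$-NN chunk over all
points, until every point is in at least one chunk (at most $n$ iterations;
empirically far fewer, since each chunk covers up to $k$ points). Points in
several chunks receive several predictions; the merged label is the
majority vote, with ties broken uniformly at random from the seeded stream.
Without ties the merge is seed-independent. An optional batch size
accelerates coverage of very large clouds; the default of one anchor per
iteration is the faithful scheme.

## Evaluation

Per class, $\mathrm{IoU}_c = \frac{TP_c}{TP_c + FP_c + FN_c}$,
$P_c = \frac{TP_c}{TP_c+FP_c}$, $R_c = \frac{TP_c}{TP_c+FN_c}$; the micro
IoU pools counts over classes (and is therefore dominated by the leaf),
the macro IoU is the unweighted mean of the defined per-class values.
A class absent from both truth and prediction has undefined metrics; we
exclude such classes from the macro mean rather than scoring them 0, and
log when that happens (the reference data never triggers it). Evaluation
is always on merged full clouds. Paired score lists (e.g. per-class IoU
across repetitions under two strategies) are compared with a two-sided
Wilcoxon signed-rank test — exact null for up to 25 untied non-zero pairs,
normal approximation with continuity correction otherwise, zero
differences dropped — labelled n.s. / * / ** / *** at 0.05 / 0.01 / 0.001.
The pairing unit is the caller's choice (we default to test cloud × class
× repetition) since conventions differ. Confidence intervals on mean IoU
across repetitions use Student-t (the convention behind 95% CI error bars
on mean-of-repetition plots).

## The synthetic plant generator

No public labelled cucumber scan set is available, so the package ships a
procedural generator (`generatePlant`). It emulates a single trellised
cucumber: a wandering vertical stem (5 mm radius), nodes (9 mm spheres) at
the internode junctions, petioles branching at phyllotactic azimuths to
drooping elliptical leaf blades (≈110 × 85 mm), curled tendril helices,
an apical growing-point cluster, ovaries hanging at the lowest nodes, and
a non-plant background of pot disc, gutter plane and support wire. Heights
are drawn from 760–1950 mm and leaf counts from 8–12, the ranges spanned
by a young greenhouse cucumber over a scanning campaign. Colours are
organ-typical RGB means with Gaussian noise (s.d. 12); stem, petiole and
node greens deliberately overlap so the node–stem confusability of real
data is reproduced. Points carry 0.8 mm isotropic jitter, the order of
laser-triangulation noise.

Per-class counts are solved by largest remainder from the target fractions
(default: the printed imbalance profile, with the unprinted residual 1.9%
split evenly over the four minority classes — a flagged assumption, not a
published value), so achieved fractions are exact to within $1/n$. Labels
follow the generating surface: there are no mislabelled points.

What the generator does **not** emulate: scanner occlusion and missing
parts, plant-to-plant architectural variation beyond height/leaf count,
colour gradients within organs, and real measurement noise physics. Tests
passing on synthetic plants therefore demonstrate the *mechanism* (the
sampling strategy changes training-set balance and downstream minority
recall) — they do not certify accuracy numbers on scanner data.

## The baseline segmenter

The slot a deep network (PointNet++ in the reference pipeline) occupies is
a two-function contract: `fitSegmenter(segmenter, views)` and
`predictSegmenter(model, view)`, where a view is a chunk's members with
positions re-centred on the anchor (translation invariance) plus colours.
The bundled baseline computes per-point features — height above the chunk
minimum, r, g, b, and covariance eigenvalue shape descriptors (linearity,
planarity, sphericity) over the 16 nearest members within the chunk — and
classifies by nearest class centroid on standardised features.
**It is deliberately weak**: fast, deterministic and sensitive to the
class composition of its training chunks, which is precisely what is
needed to measure sampling effects at desk scale. It is not a substitute
for a deep segmenter, and its absolute accuracies are meaningless as
phenotyping results. An `oracleSegmenter()` (predicts ground truth) closes
the loop in tests: with it, the whole pipeline reproduces the input
labelling exactly.

## Experiment orchestration and problem sizes

`runExperiment1` compares the two strategies at fixed $k$;
`runExperiment2` sweeps the chunk-size grid
$\{512, 1024, 2048, 4096, 8192, 16384\}$ under the class-dependent
strategy, reporting per-$k$ training entropy and classes-per-chunk
(box-plot summaries with 1.5 × IQR whiskers). Defaults follow the
reference protocol: $a = 100$, $k = 4096$, 5 repetitions, test chunking
always class-independent. A config switch (`holdPointBudget`) holds
$a \cdot k$ constant instead of $a$ — the natural alternative when one
counts points rather than chunks as training samples.

The package's own verification runs at reduced scale, chosen so the full
suite completes in minutes on one core while preserving the phenomena:
plants of 50,000 points for the directional experiments (10 seeds,
$a = 50$, $k = 512$ for the strategy comparison; 3 seeds, $a = 100$,
$k \in \{512 \ldots 4096\}$ for the sweep), and 2,000–8,000-point plants
for unit tests. At these sizes the class-dependent training set is
measurably more balanced (≈2.6 vs ≈0.8 bits) and minority-organ recall
rises sharply, mirroring the full-scale findings directionally — the
package makes no numerical claim about deep-network IoU values.

## Known limitations

* The baseline segmenter ignores long-range context; organs separable only
  by surrounding structure (petiole vs stem at equal colour) are beyond it.
* Coverage chunking with one anchor per iteration is $O(\text{chunks}
  \times n)$ distance work; for clouds far beyond $10^5$ points use the
  batch option or fewer, larger chunks.
* The generator's adjacency structure is stylised; metrics that depend on
  fine boundary geometry should not be read off synthetic plants.
* Binary PLY, LAS/LAZ and meshes are out of scope for I/O, as are
  sliding-window chunking and soft (probability-weighted) voting.
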