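# phytochunk

Class-dependent chunk sampling to battle class imbalance in the semantic
segmentation of 3D plant point clouds.

## The problem and who this is for

High-resolution scans of crop plants are segmented into organ classes
(stem, petiole, leaf, growing point, node, ovary, tendril, non-plant) as
the first step of architecture phenotyping. The data are extremely
imbalanced — leaves are ~79% of the points, each small organ well under 1% —
and chunk-based segmenters trained on such data barely learn the minority
organs, which are exactly the ones breeders care about (internodes,
fruit set, tendrils).

`phytochunk` is for researchers building or evaluating point-cloud
segmentation pipelines for plants. It implements the training-data remedy:
build each training sample ("chunk") as an anchor point plus its *k*
nearest neighbours, and allocate the *a* anchors per cloud across classes
**inversely** to the class distribution,

```
class-independent (reference):  a_c = (n_c / n) · a
class-dependent   (method):     a_c = (1 − n_c/n) / Σ_i (1 − n_i/n) · a
```

with largest-remainder rounding so Σ a_c = a exactly. Class balance is
measured as the Shannon entropy of the class fractions,
`h = −Σ p_c log2 p_c` (bits; 0 = one class, log2 C = perfectly balanced).

The package also provides: ASCII-PLY / delimited-text cloud I/O and JSON
chunk manifests; test-time **coverage chunking** (anchors drawn from
not-yet-covered points until every point is chunked) and **majority-vote
merging** of overlapping chunk predictions with seeded tie-breaks; a full
IoU / precision / recall evaluation suite with Wilcoxon signed-rank
significance labels; a procedural generator of labelled cucumber-like
clouds with controllable imbalance; a pluggable segmenter contract with a
fast nearest-centroid baseline; and orchestration of the two standard
experiments (strategy comparison, chunk-size sweep over
k ∈ {512 … 16384}).

## Worked example

```r
library(phytochunk)

pl <- generatePlant(plantParams(nPoints = 50000, seed = 1), "plant_A")  # train
te <- generatePlant(plantParams(nPoints = 50000, seed = 2), "plant_B")  # test
classDistribution(pl)
#> ClassDistribution over 50000 points, entropy 1.06 bits
#>          stem       petiole          leaf growing_point          node
#>        0.0270        0.0150        0.7890        0.0048        0.0048
#>         ovary       tendril     non_plant
#>        0.0047        0.0047        0.1500

minority <- c("growing_point", "node", "ovary", "tendril")
for (strat in c("class_independent", "class_dependent")) {
  ts <- buildTrainingSet(pl, strat, a = 50, k = 512, seed = 7)
  m  <- fitSegmenter(baselineSegmenter(), chunkViews(pl, ts$chunks[[1]]))
  pred <- predictCloud(m, te, k = 512, seed = 9)   # cover -> predict -> vote
  r  <- evaluateSegmentation(pointLabels(te), pred)
  cat(sprintf("%-17s entropy %.2f | micro IoU %.2f | macro IoU %.2f | minority mean recall %.2f\n",
              strat, ts$entropy, r@iouMicro, r@iouMacro,
              mean(r@recall[minority], na.rm = TRUE)))
}
#> class_independent entropy 0.95 | micro IoU 0.90 | macro IoU 0.43 | minority mean recall 0.44
#> class_dependent   entropy 2.54 | micro IoU 0.85 | macro IoU 0.51 | minority mean recall 0.68
```

Reading: the class-dependent training set is far more balanced (2.54 vs
0.95 bits), and with the same anchor budget the minority organs are
recovered much better (mean recall 0.68 vs 0.44, macro IoU 0.51 vs 0.43),
at a small cost in micro IoU, which is dominated by the leaf. The bundled
baseline segmenter is deliberately simple — the numbers demonstrate the
sampling mechanism, not state-of-the-art accuracy.

Published reference tables from the cucumber study that motivated the
method are bundled for worked examples:

```r
ref <- cucumberReferenceTables()
roundHalfUp(shannonEntropy(ref$fractions), 1)                    # 1.1 bits
diffNormalised(ref$independent, ref$dependent)["node", "node"]   # 46.0
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/phytochunk.R` (subcommands `simulate`, `stats`, `sample`,
`cover`, `eval`).

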