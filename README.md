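# CellGraphTMA

Tumor–stroma classification of fluorescence tissue-microarray (TMA) core
images from the DAPI nuclear channel alone.

In triple-negative breast cancer the receptor stains that normally delineate
tumor regions are absent, so tissue must be partitioned from morphology.
This package implements a cell-graph pipeline built on two regularities of
DAPI-stained cores: tumor nuclei are darker and more tightly packed than
stromal nuclei. It is aimed at image-analysis groups who want a transparent,
fully testable reference implementation of the approach.

## Method

1. **Preprocess** — flat-field (shading) correction; pixels below level 25
   zeroed; 3×3 median filter; Otsu binarization; objects under 150 px
   removed; isolated nuclei removed (bounding box + 20 px contains no other
   object); saturated overstained regions removed.
2. **Segment** — masked pixels are split at an Otsu threshold into bright
   and dark nucleus populations; each population is seeded with the regional
   maxima surviving the h-maxima transform (default h = 10) and flooded by
   seeded watershed; per-nucleus shape and intensity statistics are measured
   on the shading-corrected image.
3. **Cell graph** — nuclei *i, j* are linked iff their pixel sets dilated by
   a diamond of radius 2 intersect (equivalently, min city-block distance
   ≤ 4 px) **and** |x̄ᵢ − x̄ⱼ| < 30 intensity levels. Connected subgraphs are
   the classification units; lone nuclei go to the single-cell step.
4. **Features** — 22 per subgraph: node/edge counts, average degree,
   diameter, radius, central points, average clustering coefficient
   Cᵢ = 2Eᵢ/(kᵢ(kᵢ−1)), end-node count/percentage, hop-plot exponent
   (log–log slope of the pair count P(h) within h hops), plus means of 12
   per-nucleus shape/intensity features.
5. **Classify** — features normalized to [0, 1], ranked by the F-score
   F = [(x̄⁺−x̄)² + (x̄⁻−x̄)²] / [s²₊ + s²₋] (between-class separation over
   pooled within-class variance), top 15 into an RBF-kernel SVM.
6. **Single cells** — bright round small nuclei (roundness 4πS/w² > 0.85,
   area < 500 px) → inflammatory (stroma); strongly elongated nuclei
   (eccentricity > 0.9) → fibroblast (stroma); the rest via a per-nucleus
   SVM on the 12 node features.

A synthetic core generator (`generateCore()`) renders DAPI-like scenes with
per-nucleus ground truth — dark touching tumor nests, brighter stromal
strands with fibroblast/lymphocyte subtypes, multiplicative shading,
saturated blobs, Gaussian noise — so the entire pipeline is testable without
real slides. See the methods vignette
(`vignettes/cell-graph-tissue-classification.Rmd`) for the model details and
all parameter conventions.

## Worked example

```r
library(CellGraphTMA)

# three annotated training cores and one held-out core, all synthetic
train <- lapply(1:3, function(s) generateCore(syntheticCoreSpec(rngSeed = s)))
classifier <- trainTissueClassifier(lapply(train, `[[`, "image"),
                                    lapply(train, `[[`, "truth"))
head(classifier@ranking, 5)
#>                   feature category  f_score
#> 1                 n_nodes        T 30.50639
#> 2                avg_area        M 20.80252
#> 3 avg_equivalent_diameter        M 15.92957
#> 4       avg_max_intensity        I 13.57923
#> 5      avg_mean_intensity        I 12.99140

core <- generateCore(syntheticCoreSpec(rngSeed = 42))
res <- classifyCore(core$image, classifier)
res$nuclei
#> NucleusSet: 89 nuclei over a 512 x 512 px label image
table(res$perNucleus$class, res$perNucleus$source)
#>          fibroblast inflammatory subgraph_svm svm
#>   stroma         10           27            3   1
#>   tumor           0            0           48   0

evaluateCores(list(res), list(core$truth))
#> Classification over 1 cores:
#>   overall            100.00 (+/-    NA)
#>   tumor_producers    100.00 (+/-    NA)
#>   stroma_producers   100.00 (+/-    NA)
#>   pooled overall     100.00
```

The F-score ranking shows the expected structure: subgraph size and the
morphological/intensity averages discriminate strongly, and all 48 tumor
nuclei are recovered through subgraphs while lymphocyte- and
fibroblast-like stromal nuclei are caught by the single-cell rules.

A thin command-line front end over the same functions is installed at
`inst/cli/cellgraphtma.R` (subcommands `simulate`, `preprocess`, `segment`,
`graph`, `features`, `train`, `classify`, `evaluate`, `run`).

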