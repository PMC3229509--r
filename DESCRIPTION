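Package: CellGraphTMA
Title: Cell-Graph Based Tumor-Stroma Classification of DAPI-Stained Tissue Microarray Cores
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies tumor and stroma regions in fluorescence tissue-microarray
    (TMA) core images using only the DAPI nuclear channel. Nuclei are segmented by
    a brightness-split, h-maxima-seeded watershed; segmented nuclei are linked into
    cell graphs when they touch (diamond-dilation rule) and have compatible mean
    intensities; 22 topological, morphological and intensity features are computed
    per connected subgraph; features are ranked by F-score and the top set feeds a
    radial-basis-kernel support vector machine that labels each subgraph (and, via
    rule-based fallbacks plus a per-nucleus SVM, each isolated nucleus) as tumor or
    stroma. A synthetic core generator with per-nucleus ground truth makes the full
    pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    igraph,
    e1071,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
LinkingTo: Rcpp
biocViews: CellBasedAssays, Classification, FeatureExtraction, GraphAndNetwork, Segmentation
RoxygenNote: 7.3.3
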