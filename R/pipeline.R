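#' Pipeline configuration
#'
#' Collects every stage parameter in one list. Defaults follow the method's
#' published constants where stated (floor 25, 3x3 median, 150 px area filter,
#' 20 px isolation margin, diamond radius 2, intensity-link threshold 30,
#' top-15 feature selection); the remaining knobs (h, SVM hyperparameters,
#' single-cell thresholds, overstained blob area) are documented free
#' parameters.
#'
#' @param floor background suppression level.
#' @param medianKernel median filter kernel side (odd).
#' @param minArea small-object area filter (px).
#' @param cleanup run morphological opening/closing cleanup.
#' @param cleanupRadius structuring-element radius of the cleanup.
#' @param removeIsolated apply the isolated-nucleus filter.
#' @param isolationMargin bounding-box expansion (px per side).
#' @param saturationLevel overstained saturation level.
#' @param minBlobArea minimum overstained blob area (px).
#' @param h h-maxima height for watershed seeding.
#' @param seRadius diamond structuring-element radius of the touching rule.
#' @param intensityThreshold intensity-difference veto for linking.
#' @param topK number of F-score-selected features.
#' @param svmCost soft-margin cost C.
#' @param svmGamma RBF width; \code{NULL} = 1 / (number of selected features).
#' @param singleCells run single-cell classification of isolated nuclei.
#' @param ruleParams a [singleCellRuleParams()] list.
#' @return list of class \code{PipelineConfig}; round-trips through JSON
#'   losslessly via [writeConfig()] / [readConfig()].
#' @export
pipelineConfig <- function(floor = 25, medianKernel = 3, minArea = 150,
                           cleanup = TRUE, cleanupRadius = 1,
                           removeIsolated = TRUE, isolationMargin = 20,
                           saturationLevel = 255, minBlobArea = 2000,
                           h = 10, seRadius = 2, intensityThreshold = 30,
                           topK = 15, svmCost = 1, svmGamma = NULL,
                           singleCells = TRUE,
                           ruleParams = singleCellRuleParams()) {
  structure(list(floor = floor, medianKernel = medianKernel, minArea = minArea,
                 cleanup = cleanup, cleanupRadius = cleanupRadius,
                 removeIsolated = removeIsolated, isolationMargin = isolationMargin,
                 saturationLevel = saturationLevel, minBlobArea = minBlobArea,
                 h = h, seRadius = seRadius,
                 intensityThreshold = intensityThreshold,
                 topK = topK, svmCost = svmCost, svmGamma = svmGamma,
                 singleCells = singleCells, ruleParams = ruleParams),
            class = "PipelineConfig")
}

#' Preprocess, segment and graph one core
#'
#' Runs the full image-analysis front end: preprocessing ([preprocessCore()]),
#' nucleus segmentation ([segmentNuclei()]; statistics on the
#' shading-corrected image) and cell-graph construction
#' ([buildCellGraph()] + [connectedSubgraphs()]).
#'
#' @param image a [CoreImage-class].
#' @param config a [pipelineConfig()].
#' @param background optional flat-field (see [preprocessCore()]).
#' @return list with \code{corrected}, \code{mask}, \code{nuclei}
#'   ([NucleusSet-class]), \code{graph} ([CellGraph-class]),
#'   \code{subgraphs}, \code{isolated} and the preprocessing \code{log}.
#' @export
analyzeCore <- function(image, config = pipelineConfig(), background = NULL) {
  pre <- preprocessCore(image, config, background = background)
  nuc <- segmentNuclei(pre$corrected, pre$mask, h = config$h,
                       smoothed = pre$smoothed, minSegmentArea = config$minArea)
  graph <- buildCellGraph(nuc, radius = config$seRadius,
                          threshold = config$intensityThreshold)
  comp <- connectedSubgraphs(graph)
  list(corrected = pre$corrected, mask = pre$mask, nuclei = nuc, graph = graph,
       subgraphs = comp$subgraphs, isolated = comp$isolated, log = pre$log)
}

# per-nucleus truth class by centroid-in-tumor-mask
.nucleusTruthClasses <- function(nucleiDf, truth) {
  mask <- tumorMask(truth)
  r <- pmin(pmax(round(nucleiDf$centroid_row), 1), nrow(mask))
  c_ <- pmin(pmax(round(nucleiDf$centroid_col), 1), ncol(mask))
  ifelse(mask[cbind(r, c_)], "tumor", "stroma")
}

#' Train the tumor/stroma classifier on annotated cores
#'
#' For every training core the front end is run, each subgraph receives its
#' ground-truth label (majority of member centroids inside the tumor mask),
#' subgraph features are \code{[0, 1]}-normalized, ranked by F-score and the
#' top \code{config$topK} feed the subgraph RBF-SVM. A second, per-nucleus
#' SVM on the 12 node features is trained on all segmented nuclei (with
#' centroid-derived truth) for single-cell classification.
#'
#' @param cores list of [CoreImage-class]s.
#' @param truths list of matching [GroundTruth-class]s.
#' @param config a [pipelineConfig()].
#' @return A [TissueClassifier-class].
#' @export
trainTissueClassifier <- function(cores, truths, config = pipelineConfig()) {
  stopifnot(length(cores) == length(truths), length(cores) >= 1)
  gFeats <- list(); gLabels <- character(0)
  nFeats <- list(); nLabels <- character(0)
  for (i in seq_along(cores)) {
    an <- analyzeCore(cores[[i]], config)
    if (length(an$subgraphs)) {
      fm <- featureMatrix(an$subgraphs)
      fm$subgraph_id <- NULL
      gFeats[[length(gFeats) + 1L]] <- fm
      gLabels <- c(gLabels, vapply(an$subgraphs, assignTruthLabel,
                                   character(1), truth = truths[[i]]))
    }
    nd <- nuclei(an$nuclei)
    if (nrow(nd)) {
      nf <- nodeFeatureMatrix(nd)
      nf$label <- NULL
      nFeats[[length(nFeats) + 1L]] <- nf
      nLabels <- c(nLabels, .nucleusTruthClasses(nd, truths[[i]]))
    }
  }
  gX <- do.call(rbind, gFeats)
  if (is.null(gX) || length(unique(gLabels)) < 2) {
    stop("training requires subgraphs of both classes across the training cores")
  }
  norm <- normalizeFeatures(gX)
  k <- min(config$topK, ncol(norm$x))
  rk <- rankAndSelect(norm$x, gLabels, k = k)
  gamma <- if (is.null(config$svmGamma)) 1 / k else config$svmGamma
  gModel <- trainTissueSVM(norm$x[, rk$selected, drop = FALSE], gLabels,
                           C = config$svmCost, gamma = gamma)
  nX <- do.call(rbind, nFeats)
  nModel <- list(); nBounds <- data.frame()
  if (!is.null(nX) && length(unique(nLabels)) >= 2) {
    nNorm <- normalizeFeatures(nX)
    nModel <- trainTissueSVM(nNorm$x, nLabels, C = config$svmCost,
                             gamma = 1 / ncol(nNorm$x))
    nBounds <- nNorm$bounds
  }
  new("TissueClassifier", graphModel = unclass(gModel), nodeModel = unclass(nModel),
      graphBounds = norm$bounds, nodeBounds = nBounds,
      selectedFeatures = rk$selected, ranking = rk$ranking,
      config = unclass(config))
}

#' Classify one core
#'
#' Runs the front end, labels every subgraph with the subgraph SVM and
#' propagates labels to member nuclei; when single-cell classification is
#' enabled, isolated nuclei are labeled by the rules + per-nucleus SVM.
#' Enabling single cells never changes any subgraph's label — it only adds
#' labels for nuclei that had none.
#'
#' @param image a [CoreImage-class].
#' @param classifier a [TissueClassifier-class].
#' @param config a [pipelineConfig()]; defaults to the classifier's training
#'   configuration.
#' @return list with \code{perNucleus} (data.frame: \code{label},
#'   \code{class}, \code{source}), \code{subgraphLabels}, \code{nuclei}
#'   ([NucleusSet-class]), \code{subgraphs}, \code{isolated}, \code{log}.
#' @export
classifyCore <- function(image, classifier, config = NULL) {
  if (is.null(config)) config <- do.call(pipelineConfig, classifier@config)
  an <- analyzeCore(image, config)
  scls <- classifySubgraphs(classifier, an$subgraphs)
  perNuc <- scls$perNucleus[, c("label", "class", "source")]
  if (isTRUE(config$singleCells) && nrow(an$isolated)) {
    nm <- if (length(classifier@nodeModel)) {
      structure(classifier@nodeModel, class = "rbfSVM")
    } else NULL
    sc <- classifySingleCells(an$isolated, params = config$ruleParams,
                              nodeModel = nm, nodeBounds = classifier@nodeBounds,
                              referenceMeans = nuclei(an$nuclei)$mean_intensity)
    perNuc <- rbind(perNuc, sc)
  }
  perNuc <- perNuc[order(perNuc$label), , drop = FALSE]
  rownames(perNuc) <- NULL
  list(perNucleus = perNuc, subgraphLabels = scls$subgraphLabels,
       nuclei = an$nuclei, subgraphs = an$subgraphs, isolated = an$isolated,
       log = an$log)
}

#' Evaluate predicted per-nucleus labels against ground truth
#'
#' Matches each segmented nucleus to its truth class by centroid position in
#' the tumor-region mask, then scores with [evaluateClassification()].
#'
#' @param results list of [classifyCore()] results (one per core).
#' @param truths list of matching [GroundTruth-class]s.
#' @return A \code{ClassificationReport}.
#' @export
evaluateCores <- function(results, truths) {
  stopifnot(length(results) == length(truths))
  pred <- character(0); tru <- character(0); core <- integer(0)
  for (i in seq_along(results)) {
    pn <- results[[i]]$perNucleus
    nd <- nuclei(results[[i]]$nuclei)
    nd <- nd[match(pn$label, nd$label), , drop = FALSE]
    tcls <- .nucleusTruthClasses(nd, truths[[i]])
    pred <- c(pred, pn$class); tru <- c(tru, tcls)
    core <- c(core, rep(i, nrow(pn)))
  }
  evaluateClassification(pred, tru, core)
}

#' Run the full pipeline on image files
#'
#' File-level orchestration: reads each core image, runs
#' [classifyCore()] (or only the front end when no classifier is given),
#' writes per-core artifacts (16-bit label TIFF, nucleus statistics CSV,
#' subgraph feature CSV, per-nucleus label CSV, classification overlay PNG)
#' plus a JSON manifest, and optionally a report against ground truth.
#' Re-running with identical inputs and configuration reproduces the
#' artifacts bit for bit.
#'
#' @param imagePaths character vector of 8-bit grayscale TIFF/PNG paths.
#' @param outDir output directory (created if needed).
#' @param classifier optional [TissueClassifier-class].
#' @param config a [pipelineConfig()].
#' @param truthPaths optional character vector of ground-truth label TIFFs
#'   with sidecar CSVs (see [writeGroundTruth()]).
#' @param stopAfter one of \code{"segment"}, \code{"graph"},
#'   \code{"classify"}: stage gating.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(imagePaths, outDir, classifier = NULL,
                        config = pipelineConfig(), truthPaths = NULL,
                        stopAfter = c("classify", "graph", "segment")) {
  stopAfter <- match.arg(stopAfter)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(cores = list())
  results <- list(); truths <- list()
  for (i in seq_along(imagePaths)) {
    path <- imagePaths[i]
    if (!file.exists(path)) stop("input image not found: ", path)
    img <- readCoreImage(path)
    stem <- sub("\\.[^.]+$", "", basename(path))
    arts <- list(image = basename(path))
    an <- analyzeCore(img, config)
    labPath <- file.path(outDir, paste0(stem, "_labels.tif"))
    writeLabelImage(labelImage(an$nuclei), labPath)
    nucPath <- file.path(outDir, paste0(stem, "_nuclei.csv"))
    write.csv(nuclei(an$nuclei), nucPath, row.names = FALSE)
    arts$labels <- basename(labPath); arts$nuclei <- basename(nucPath)
    if (stopAfter != "segment") {
      featPath <- file.path(outDir, paste0(stem, "_features.csv"))
      write.csv(featureMatrix(an$subgraphs), featPath, row.names = FALSE)
      edgePath <- file.path(outDir, paste0(stem, "_edges.csv"))
      e <- graphEdges(an$graph)
      write.csv(data.frame(node_label_a = e[, 1], node_label_b = e[, 2]),
                edgePath, row.names = FALSE)
      arts$features <- basename(featPath); arts$edges <- basename(edgePath)
    }
    if (stopAfter == "classify" && !is.null(classifier)) {
      res <- classifyCore(img, classifier, config)
      clsPath <- file.path(outDir, paste0(stem, "_classes.csv"))
      write.csv(res$perNucleus, clsPath, row.names = FALSE)
      ovPath <- file.path(outDir, paste0(stem, "_overlay.png"))
      writeClassOverlay(labelImage(res$nuclei), res$perNucleus, ovPath)
      arts$classes <- basename(clsPath); arts$overlay <- basename(ovPath)
      results[[length(results) + 1L]] <- res
      if (!is.null(truthPaths)) {
        truths[[length(truths) + 1L]] <- readGroundTruth(truthPaths[i])
      }
    }
    manifest$cores[[stem]] <- arts
  }
  if (length(results) && length(truths) == length(results)) {
    rep <- evaluateCores(results, truths)
    repPath <- file.path(outDir, "report.json")
    jsonlite::write_json(list(per_core = rep$per_core, aggregate = rep$aggregate,
                              pooled_overall = rep$pooled_overall),
                         repPath, dataframe = "rows", auto_unbox = TRUE, digits = NA)
    manifest$report <- basename(repPath)
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
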