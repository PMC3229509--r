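#' Parameters of the rule-based single-cell classifiers
#'
#' Thresholds for the inflammatory-cell rule (intensity, roundness, area) and
#' the fibroblast rule (eccentricity). The intensity threshold may be left
#' \code{NULL}, in which case it is derived per core as the Otsu threshold of
#' the nucleus mean intensities plus 30 levels (inflammatory nuclei are much
#' brighter than anything else on the core).
#'
#' @param intensityThreshold 8-bit level; \code{NULL} = per-core automatic.
#' @param roundnessThreshold isoperimetric roundness \eqn{4\pi S / w^2} cut;
#'   default 0.85.
#' @param maxInflammatoryArea area cut in pixels; default 500.
#' @param eccentricityThreshold fibroblast eccentricity cut in (0, 1);
#'   default 0.9.
#' @return list of class \code{SingleCellRuleParams}.
#' @export
singleCellRuleParams <- function(intensityThreshold = NULL,
                                 roundnessThreshold = 0.85,
                                 maxInflammatoryArea = 500,
                                 eccentricityThreshold = 0.9) {
  stopifnot(roundnessThreshold > 0, roundnessThreshold <= 1,
            maxInflammatoryArea > 0,
            eccentricityThreshold > 0, eccentricityThreshold < 1)
  structure(list(intensityThreshold = intensityThreshold,
                 roundnessThreshold = roundnessThreshold,
                 maxInflammatoryArea = maxInflammatoryArea,
                 eccentricityThreshold = eccentricityThreshold),
            class = "SingleCellRuleParams")
}

#' Inflammatory-cell rule
#'
#' A nucleus is called inflammatory (lymphocyte-like) when its mean intensity
#' exceeds the intensity threshold, its isoperimetric roundness
#' \eqn{4\pi S / w^2} (S = area, w = perimeter) exceeds the roundness
#' threshold, and its area is below 500 px: small, round and very bright.
#'
#' @param nucleus one row of a [NucleusSet-class] statistics table (or a
#'   data.frame of rows, vectorized).
#' @param params a [singleCellRuleParams()] list; \code{intensityThreshold}
#'   must be resolved (non-\code{NULL}).
#' @return logical vector.
#' @export
isInflammatory <- function(nucleus, params = singleCellRuleParams(intensityThreshold = 200)) {
  if (is.null(params$intensityThreshold)) {
    stop("intensityThreshold must be resolved before applying the rule")
  }
  if (any(nucleus$perimeter <= 0)) stop("nucleus perimeter must be positive")
  roundness <- 4 * pi * nucleus$area / nucleus$perimeter^2
  nucleus$mean_intensity > params$intensityThreshold &
    roundness > params$roundnessThreshold &
    nucleus$area < params$maxInflammatoryArea
}

#' Fibroblast rule
#'
#' Fibroblast nuclei are strongly elongated: classified when the ellipse
#' eccentricity \eqn{\sqrt{1 - (d_{min}/d_{max})^2}} exceeds the threshold.
#'
#' @inheritParams isInflammatory
#' @return logical vector.
#' @export
isFibroblast <- function(nucleus, params = singleCellRuleParams(intensityThreshold = 200)) {
  if (any(nucleus$major_axis <= 0)) stop("nucleus major axis must be positive")
  nucleus$eccentricity > params$eccentricityThreshold
}

#' Classify isolated nuclei
#'
#' Nuclei left unlinked by the cell-graph step are classified one by one:
#' first the inflammatory rule, then the fibroblast rule (both assign stroma),
#' and the remainder by the per-nucleus SVM on the 12 morphological/intensity
#' node features. Every nucleus receives exactly one label; the rule order is
#' fixed and deterministic.
#'
#' @param isolated data.frame of isolated-nucleus statistics (rows of a
#'   [NucleusSet-class] table).
#' @param params a [singleCellRuleParams()] list; a \code{NULL} intensity
#'   threshold is resolved from \code{referenceMeans}.
#' @param nodeModel per-nucleus \code{rbfSVM} (see [trainTissueSVM()]), or
#'   \code{NULL} when every nucleus is expected to hit a rule.
#' @param nodeBounds normalization bounds for the node features.
#' @param referenceMeans mean intensities of all nuclei of the core, used to
#'   resolve an automatic intensity threshold (Otsu + 30).
#' @return data.frame: \code{label}, \code{class}, \code{source} in
#'   \code{c("inflammatory", "fibroblast", "svm")}.
#' @export
classifySingleCells <- function(isolated, params = singleCellRuleParams(),
                                nodeModel = NULL, nodeBounds = NULL,
                                referenceMeans = NULL) {
  if (!nrow(isolated)) {
    return(data.frame(label = integer(0), class = character(0), source = character(0)))
  }
  if (is.null(params$intensityThreshold)) {
    if (is.null(referenceMeans)) referenceMeans <- isolated$mean_intensity
    params$intensityThreshold <- .otsuFromValues(round(referenceMeans)) + 30
  }
  cls <- rep(NA_character_, nrow(isolated))
  src <- rep(NA_character_, nrow(isolated))
  infl <- isInflammatory(isolated, params)
  cls[infl] <- "stroma"; src[infl] <- "inflammatory"
  fib <- !infl & isFibroblast(isolated, params)
  cls[fib] <- "stroma"; src[fib] <- "fibroblast"
  rest <- is.na(cls)
  if (any(rest)) {
    if (is.null(nodeModel)) stop("node model required: some nuclei match no rule")
    feats <- nodeFeatureMatrix(isolated[rest, , drop = FALSE])
    norm <- normalizeFeatures(feats[, setdiff(names(feats), "label"), drop = FALSE],
                              bounds = nodeBounds)
    cls[rest] <- svmPredict(nodeModel, norm$x)
    src[rest] <- "svm"
  }
  data.frame(label = isolated$label, class = cls, source = src)
}
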