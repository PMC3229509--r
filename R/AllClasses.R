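#' @import methods
#' @importFrom stats median sd lm coef predict rnorm runif setNames
#' @importFrom utils read.csv write.csv head
NULL

#' CoreImage: a single-channel 8-bit TMA core image
#'
#' Holds the DAPI channel of one tissue-microarray core as an integer matrix of
#' intensities in \code{[0, 255]} (rows are image rows), together with optional
#' pixel-size metadata and, when the image comes from the synthetic generator or
#' from a flat-field calibration exposure, a multiplicative shading field.
#'
#' @slot pixels integer matrix, intensities in \code{[0, 255]}.
#' @slot pixelSize numeric(1), physical pixel edge length in micrometres
#'   (\code{NA_real_} when unknown).
#' @slot calibration numeric matrix with the multiplicative flat-field
#'   (same dimensions as \code{pixels}) or a 0x0 matrix when absent.
#'
#' @seealso [coreImage()], [pixels()], [generateCore()]
#' @export
setClass("CoreImage",
  representation(pixels = "matrix", pixelSize = "numeric", calibration = "matrix"),
  prototype(pixels = matrix(0L, 0, 0), pixelSize = NA_real_,
            calibration = matrix(numeric(0), 0, 0))
)

setValidity("CoreImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric/integer matrix")
  if (length(p) && (min(p) < 0 || max(p) > 255)) {
    return("pixel intensities must lie in [0, 255]")
  }
  if (length(p) && any(p != round(p))) return("pixel intensities must be integral")
  if (length(object@calibration) &&
      !identical(dim(object@calibration), dim(p))) {
    return("calibration field must match image dimensions")
  }
  if (length(object@pixelSize) != 1) return("pixelSize must be length 1")
  TRUE
})

#' Construct a CoreImage
#'
#' @param pixels numeric or integer matrix with values in \code{[0, 255]};
#'   values are rounded and stored as integers.
#' @param pixelSize physical pixel size in micrometres per pixel (optional).
#' @param calibration optional multiplicative flat-field matrix.
#' @return A [CoreImage-class] object.
#' @examples
#' img <- coreImage(matrix(100L, 8, 8))
#' dim(pixels(img))
#' @export
coreImage <- function(pixels, pixelSize = NA_real_, calibration = matrix(numeric(0), 0, 0)) {
  storage.mode(pixels) <- "integer"
  new("CoreImage", pixels = pixels, pixelSize = as.numeric(pixelSize),
      calibration = calibration)
}

#' GroundTruth: per-nucleus truth for a (synthetic) core
#'
#' The reference against which segmentation and classification are scored: a
#' label image (0 = background, k = nucleus k), a tumor/stroma class and a
#' subtype per nucleus, and the binary tumor-region mask standing in for a
#' manual keratin/vimentin-based tissue annotation.
#'
#' @slot labels integer matrix of nucleus labels.
#' @slot classes named character vector (\code{"tumor"}/\code{"stroma"}),
#'   names are nucleus labels.
#' @slot subtypes named character vector
#'   (\code{"tumor"}, \code{"fibroblast"}, \code{"lymphocyte"},
#'   \code{"generic_stroma"}), names are nucleus labels.
#' @slot tumorMask logical matrix marking the tumor region.
#' @export
setClass("GroundTruth",
  representation(labels = "matrix", classes = "character",
                 subtypes = "character", tumorMask = "matrix")
)

setValidity("GroundTruth", function(object) {
  labs <- sort(unique(as.integer(object@labels)))
  labs <- labs[labs > 0L]
  if (!identical(dim(object@labels), dim(object@tumorMask))) {
    return("labels and tumorMask must share dimensions")
  }
  if (!setequal(as.character(labs), names(object@classes))) {
    return("every nonzero label must have exactly one class entry")
  }
  if (!all(object@classes %in% c("tumor", "stroma"))) {
    return("classes must be 'tumor' or 'stroma'")
  }
  if (!setequal(names(object@classes), names(object@subtypes))) {
    return("classes and subtypes must cover the same labels")
  }
  TRUE
})

groundTruth <- function(labels, classes, subtypes, tumorMask) {
  storage.mode(labels) <- "integer"
  new("GroundTruth", labels = labels, classes = classes,
      subtypes = subtypes, tumorMask = tumorMask)
}

#' NucleusSet: segmented nuclei of one core
#'
#' The result of watershed segmentation: a label image partitioning the nucleus
#' mask, and one row of shape/intensity statistics per nucleus (the per-cell
#' quantities behind the averaged node features and the single-cell rules).
#'
#' The statistics table has columns \code{label}, \code{area},
#' \code{centroid_row}, \code{centroid_col}, \code{bbox_min_row},
#' \code{bbox_min_col}, \code{bbox_max_row}, \code{bbox_max_col},
#' \code{mean_intensity}, \code{min_intensity}, \code{max_intensity},
#' \code{median_intensity}, \code{std_intensity}, \code{major_axis},
#' \code{minor_axis}, \code{eccentricity}, \code{equivalent_diameter},
#' \code{extent}, \code{perimeter}.
#'
#' @slot labels integer label matrix (0 = background).
#' @slot nuclei data.frame of per-nucleus statistics, one row per label.
#' @export
setClass("NucleusSet",
  representation(labels = "matrix", nuclei = "data.frame")
)

setValidity("NucleusSet", function(object) {
  n <- object@nuclei
  if (nrow(n)) {
    if (any(n$area < 1)) return("every nucleus must contain >= 1 pixel")
    bad <- n$min_intensity > n$median_intensity | n$median_intensity > n$max_intensity
    if (any(bad)) return("intensity statistics must satisfy min <= median <= max")
    if (any(n$minor_axis > n$major_axis + 1e-9)) {
      return("minor axis must not exceed major axis")
    }
    if (any(n$eccentricity < -1e-9 | n$eccentricity > 1 + 1e-9)) {
      return("eccentricity must lie in [0, 1]")
    }
    if (any(n$extent <= 0 | n$extent > 1 + 1e-9)) return("extent must lie in (0, 1]")
  }
  TRUE
})

nucleusSet <- function(labels, nuclei) {
  storage.mode(labels) <- "integer"
  new("NucleusSet", labels = labels, nuclei = nuclei)
}

#' CellGraph: nuclei linked by touching + intensity compatibility
#'
#' An undirected graph whose nodes are segmented nuclei and whose edges join
#' nuclei that touch after diamond dilation and whose mean intensities differ
#' by less than the linking threshold.
#'
#' @slot nodes data.frame of member nuclei (same columns as the
#'   [NucleusSet-class] statistics table).
#' @slot edges two-column integer matrix of node labels (each row one
#'   undirected edge, smaller label first, no duplicates, no self-loops).
#' @export
setClass("CellGraph",
  representation(nodes = "data.frame", edges = "matrix")
)

setValidity("CellGraph", function(object) {
  e <- object@edges
  if (ncol(e) != 2 && length(e)) return("edges must have two columns")
  if (nrow(e)) {
    if (any(e[, 1] == e[, 2])) return("self-loops are not allowed")
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    if (anyDuplicated(key)) return("duplicate edges are not allowed")
    if (!all(e %in% object@nodes$label)) return("edges must reference member nodes")
  }
  TRUE
})

cellGraph <- function(nodes, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  new("CellGraph", nodes = nodes, edges = edges)
}

#' TissueClassifier: trained tumor/stroma model bundle
#'
#' Everything needed to classify a new core: the subgraph-level RBF-SVM with its
#' feature normalization bounds and F-score-selected feature set, the
#' per-nucleus SVM used by single-cell classification, and the configuration the
#' models were trained under.
#'
#' @slot graphModel list with the subgraph SVM (support vectors, coefficients,
#'   bias, gamma) as stored by [trainTissueSVM()].
#' @slot nodeModel per-nucleus SVM in the same format, or empty list.
#' @slot graphBounds data.frame of per-feature training min/max for subgraph
#'   features.
#' @slot nodeBounds data.frame of per-feature training min/max for node features.
#' @slot selectedFeatures character vector of the F-score-selected subgraph
#'   features, in rank order.
#' @slot ranking data.frame with the full F-score ranking
#'   (feature, category, f_score).
#' @slot config list of pipeline parameters used in training.
#' @export
setClass("TissueClassifier",
  representation(graphModel = "list", nodeModel = "list",
                 graphBounds = "data.frame", nodeBounds = "data.frame",
                 selectedFeatures = "character", ranking = "data.frame",
                 config = "list")
)
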