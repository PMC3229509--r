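#' Access the pixel matrix of a CoreImage
#'
#' @param x a [CoreImage-class].
#' @return integer matrix of intensities in \code{[0, 255]}.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "CoreImage", function(x) x@pixels)

#' Pixel size metadata (micrometres per pixel)
#'
#' @param x a [CoreImage-class].
#' @return numeric(1), possibly \code{NA}.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "CoreImage", function(x) x@pixelSize)

#' Flat-field calibration attached to an image
#'
#' @param x a [CoreImage-class].
#' @return numeric matrix (0x0 when no calibration is attached).
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' @rdname calibration
#' @export
setMethod("calibration", "CoreImage", function(x) x@calibration)

#' Label image of a segmentation or ground truth
#'
#' @param x a [NucleusSet-class] or [GroundTruth-class].
#' @return integer matrix, 0 = background, k = nucleus k.
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))

#' @rdname labelImage
#' @export
setMethod("labelImage", "NucleusSet", function(x) x@labels)

#' @rdname labelImage
#' @export
setMethod("labelImage", "GroundTruth", function(x) x@labels)

#' Per-nucleus statistics table
#'
#' @param x a [NucleusSet-class].
#' @return data.frame, one row per nucleus.
#' @export
setGeneric("nuclei", function(x) standardGeneric("nuclei"))

#' @rdname nuclei
#' @export
setMethod("nuclei", "NucleusSet", function(x) x@nuclei)

#' Nucleus classes of a ground truth
#'
#' @param x a [GroundTruth-class].
#' @return named character vector (\code{"tumor"}/\code{"stroma"}).
#' @export
setGeneric("nucleusClasses", function(x) standardGeneric("nucleusClasses"))

#' @rdname nucleusClasses
#' @export
setMethod("nucleusClasses", "GroundTruth", function(x) x@classes)

#' Nucleus subtypes of a ground truth
#'
#' @param x a [GroundTruth-class].
#' @return named character vector.
#' @export
setGeneric("nucleusSubtypes", function(x) standardGeneric("nucleusSubtypes"))

#' @rdname nucleusSubtypes
#' @export
setMethod("nucleusSubtypes", "GroundTruth", function(x) x@subtypes)

#' Tumor-region mask of a ground truth
#'
#' @param x a [GroundTruth-class].
#' @return logical matrix.
#' @export
setGeneric("tumorMask", function(x) standardGeneric("tumorMask"))

#' @rdname tumorMask
#' @export
setMethod("tumorMask", "GroundTruth", function(x) x@tumorMask)

#' Nodes of a cell graph
#'
#' @param x a [CellGraph-class].
#' @return data.frame of member nuclei.
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname graphNodes
#' @export
setMethod("graphNodes", "CellGraph", function(x) x@nodes)

#' Edges of a cell graph
#'
#' @param x a [CellGraph-class].
#' @return two-column integer matrix of node labels.
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname graphEdges
#' @export
setMethod("graphEdges", "CellGraph", function(x) x@edges)

setMethod("show", "CoreImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CoreImage: %d x %d px", d[1], d[2]))
  if (!is.na(object@pixelSize)) cat(sprintf(" (%.3g um/px)", object@pixelSize))
  if (length(object@calibration)) cat(", with flat-field calibration")
  cat(sprintf("\n  intensity range [%d, %d]\n",
              if (length(object@pixels)) min(object@pixels) else 0L,
              if (length(object@pixels)) max(object@pixels) else 0L))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d nuclei (%d tumor, %d stroma), %d x %d px\n",
              length(object@classes), sum(object@classes == "tumor"),
              sum(object@classes == "stroma"),
              nrow(object@labels), ncol(object@labels)))
})

setMethod("show", "NucleusSet", function(object) {
  cat(sprintf("NucleusSet: %d nuclei over a %d x %d px label image\n",
              nrow(object@nuclei), nrow(object@labels), ncol(object@labels)))
})

setMethod("show", "CellGraph", function(object) {
  cat(sprintf("CellGraph: %d nodes, %d edges\n",
              nrow(object@nodes), nrow(object@edges)))
})

setMethod("show", "TissueClassifier", function(object) {
  cat(sprintf("TissueClassifier: %d selected subgraph features, %s node model\n",
              length(object@selectedFeatures),
              if (length(object@nodeModel)) "with" else "without"))
})
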