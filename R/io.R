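#' Read an 8-bit grayscale core image
#'
#' @param path a TIFF or PNG file.
#' @param pixelSize optional micrometres-per-pixel metadata to attach.
#' @return A [CoreImage-class].
#' @export
readCoreImage <- function(path, pixelSize = NA_real_) {
  if (!file.exists(path)) stop("input image not found: ", path)
  m <- .readGray(path)
  coreImage(round(m * 255), pixelSize = pixelSize)
}

.readGray <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  m <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}

#' Write a CoreImage as 8-bit grayscale
#'
#' @param image a [CoreImage-class] or matrix.
#' @param path output path ending in .tif/.tiff or .png.
#' @return invisibly, \code{path}.
#' @export
writeCoreImage <- function(image, path) {
  px <- .asPixelMatrix(image) / 255
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = 8),
    png = png::writePNG(px, path),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

#' Write a label image as 16-bit TIFF
#'
#' @param labels integer matrix (values up to 65535).
#' @param path output .tif path.
#' @return invisibly, \code{path}.
#' @export
writeLabelImage <- function(labels, path) {
  stopifnot(max(labels) <= 65535)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a 16-bit label TIFF
#'
#' @param path the file written by [writeLabelImage()].
#' @return integer label matrix.
#' @export
readLabelImage <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  out <- round(m * 65535)
  storage.mode(out) <- "integer"
  out
}

#' Write ground truth to disk
#'
#' Writes three sibling files: \code{<stem>_gtlabels.tif} (16-bit label
#' image), \code{<stem>_gt.csv} (label, class, subtype, centroid_row,
#' centroid_col) and \code{<stem>_gtmask.tif} (binary tumor-region mask).
#'
#' @param truth a [GroundTruth-class].
#' @param stem path prefix.
#' @return invisibly, \code{stem}.
#' @export
writeGroundTruth <- function(truth, stem) {
  lab <- labelImage(truth)
  writeLabelImage(lab, paste0(stem, "_gtlabels.tif"))
  ids <- as.integer(names(nucleusClasses(truth)))
  cr <- numeric(length(ids)); cc <- numeric(length(ids))
  if (length(ids)) {
    idx <- which(lab > 0L)
    l <- lab[idx]
    nr <- nrow(lab)
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    cr <- rowsum(as.numeric(rows), l)[, 1] / tabulate(l)[sort(unique(l))]
    cc <- rowsum(as.numeric(cols), l)[, 1] / tabulate(l)[sort(unique(l))]
  }
  df <- data.frame(label = ids,
                   class = unname(nucleusClasses(truth)[as.character(ids)]),
                   subtype = unname(nucleusSubtypes(truth)[as.character(ids)]),
                   centroid_row = unname(cr), centroid_col = unname(cc))
  write.csv(df, paste0(stem, "_gt.csv"), row.names = FALSE)
  tiff::writeTIFF(tumorMask(truth) * 1, paste0(stem, "_gtmask.tif"),
                  bits.per.sample = 8)
  invisible(stem)
}

#' Read ground truth written by [writeGroundTruth()]
#'
#' @param stem the path prefix used when writing.
#' @return A [GroundTruth-class].
#' @export
readGroundTruth <- function(stem) {
  lab <- readLabelImage(paste0(stem, "_gtlabels.tif"))
  df <- read.csv(paste0(stem, "_gt.csv"))
  m <- tiff::readTIFF(paste0(stem, "_gtmask.tif"))
  if (length(dim(m)) == 3) m <- m[, , 1]
  groundTruth(lab,
              classes = setNames(as.character(df$class), df$label),
              subtypes = setNames(as.character(df$subtype), df$label),
              tumorMask = m > 0.5)
}

#' Write the classification overlay image
#'
#' Renders nucleus pixels in the conventional colors — green for tumor, blue
#' for stroma — on a black background.
#'
#' @param labels integer label matrix of the segmentation.
#' @param perNucleus data.frame with \code{label} and \code{class}.
#' @param path output .png path.
#' @return invisibly, \code{path}.
#' @export
writeClassOverlay <- function(labels, perNucleus, path) {
  nr <- nrow(labels); nc <- ncol(labels)
  rgb <- array(0, dim = c(nr, nc, 3))
  cls <- setNames(perNucleus$class, perNucleus$label)
  sel <- labels > 0L
  labv <- labels[sel]
  known <- as.character(labv) %in% names(cls)
  g <- matrix(0, nr, nc); b <- matrix(0, nr, nc)
  gv <- rep(0, length(labv)); bv <- rep(0, length(labv))
  cl <- rep(NA_character_, length(labv))
  cl[known] <- cls[as.character(labv[known])]
  gv[!is.na(cl) & cl == "tumor"] <- 1
  bv[!is.na(cl) & cl == "stroma"] <- 1
  g[sel] <- gv; b[sel] <- bv
  rgb[, , 2] <- g; rgb[, , 3] <- b
  png::writePNG(rgb, path)
  invisible(path)
}

#' Serialize a trained classifier to versioned JSON
#'
#' Stores kernel parameters, support vectors, coefficients, normalization
#' bounds, the selected feature set, the F-score ranking and the training
#' configuration; [readTissueClassifier()] restores a model that predicts
#' identically.
#'
#' @param classifier a [TissueClassifier-class].
#' @param path output .json path.
#' @return invisibly, \code{path}.
#' @export
writeTissueClassifier <- function(classifier, path) {
  cfg <- classifier@config
  cfg$ruleParams <- unclass(cfg$ruleParams)
  payload <- list(
    format = "CellGraphTMA-model", version = 1L,
    graphModel = classifier@graphModel,
    nodeModel = classifier@nodeModel,
    graphBounds = classifier@graphBounds,
    nodeBounds = classifier@nodeBounds,
    selectedFeatures = classifier@selectedFeatures,
    ranking = classifier@ranking,
    config = cfg
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Restore a classifier from JSON
#'
#' @param path file written by [writeTissueClassifier()].
#' @return A [TissueClassifier-class].
#' @export
readTissueClassifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "CellGraphTMA-model")) stop("not a classifier file: ", path)
  fixModel <- function(m) {
    if (!length(m)) return(list())
    if (!is.matrix(m$SV)) m$SV <- do.call(rbind, lapply(m$SV, as.numeric))
    m$coefs <- as.numeric(m$coefs)
    m
  }
  cfg <- p$config
  cfg$ruleParams <- do.call(singleCellRuleParams, c(cfg$ruleParams))
  new("TissueClassifier",
      graphModel = fixModel(p$graphModel),
      nodeModel = fixModel(p$nodeModel),
      graphBounds = as.data.frame(p$graphBounds),
      nodeBounds = as.data.frame(p$nodeBounds),
      selectedFeatures = as.character(p$selectedFeatures),
      ranking = as.data.frame(p$ranking),
      config = cfg)
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [pipelineConfig()].
#' @param path .json path.
#' @return invisibly \code{path} ([writeConfig()]); a \code{PipelineConfig}
#'   ([readConfig()]).
#' @export
writeConfig <- function(config, path) {
  cfg <- unclass(config)
  cfg$ruleParams <- unclass(cfg$ruleParams)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$ruleParams <- do.call(singleCellRuleParams, c(p$ruleParams))
  do.call(pipelineConfig, p)
}
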