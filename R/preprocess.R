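#' Flat-field (shading) correction
#'
#' Compensates multiplicative shading — lens vignetting, uneven illumination,
#' mounting-medium autofluorescence — by dividing the image by a normalized
#' flat-field. The field is either supplied (a calibration exposure, or the
#' field attached to a synthetic [CoreImage-class]) or estimated from the image
#' itself by fitting a quadratic polynomial surface to block-wise robust means
#' of the stained (foreground) pixels.
#'
#' @param image a [CoreImage-class] or integer matrix in \code{[0, 255]}.
#' @param background optional flat-field estimate: a [CoreImage-class] or
#'   numeric matrix of the same dimensions. When \code{NULL} the field is
#'   estimated from the image.
#' @param floor intensity level below which pixels are treated as unstained
#'   background during field estimation.
#' @param blockSize edge length (px) of the estimation grid blocks.
#' @return A [CoreImage-class] with the compensated, rounded, clipped image.
#'   A perfectly flat field leaves the image unchanged up to rounding.
#' @examples
#' img <- coreImage(matrix(100L, 16, 16))
#' all(pixels(shadingCorrect(img, matrix(1, 16, 16))) == 100L)
#' @export
shadingCorrect <- function(image, background = NULL, floor = 25, blockSize = 64) {
  px <- .asPixelMatrix(image)
  ps <- if (is(image, "CoreImage")) pixelSize(image) else NA_real_
  if (is.null(background)) {
    field <- .estimateShadingField(px, floor = floor, blockSize = blockSize)
  } else {
    field <- if (is(background, "CoreImage")) pixels(background) else background
    field <- field + 0.0
    if (!identical(dim(field), dim(px))) {
      stop("background estimate must match image dimensions")
    }
    if (all(field == 0)) stop("degenerate background estimate: all zero")
    field <- field / mean(field)
  }
  field[field <= 0] <- min(field[field > 0])
  out <- pmin(pmax(round(px / field), 0), 255)
  coreImage(out, pixelSize = ps)
}

# Quadratic-surface shading estimate from block-wise foreground medians.
.estimateShadingField <- function(px, floor = 25, blockSize = 64) {
  nr <- nrow(px); nc <- ncol(px)
  ri <- pmin((seq_len(nr) - 1L) %/% blockSize + 1L, max(1L, nr %/% blockSize))
  ci <- pmin((seq_len(nc) - 1L) %/% blockSize + 1L, max(1L, nc %/% blockSize))
  fg <- px >= floor
  if (!any(fg)) stop("cannot estimate shading: no foreground pixels")
  idx <- which(fg, arr.ind = TRUE)
  blk <- paste(ri[idx[, 1]], ci[idx[, 2]])
  vals <- split(px[fg], blk)
  keep <- lengths(vals) >= 30         # blocks with too few stained px are noise
  if (sum(keep) < 6) {                # not enough support for a quadratic fit
    return(matrix(1, nr, nc))
  }
  med <- vapply(vals[keep], stats::median, numeric(1))
  ctr <- do.call(rbind, strsplit(names(med), " "))
  br <- (as.integer(ctr[, 1]) - 0.5) * blockSize
  bc <- (as.integer(ctr[, 2]) - 0.5) * blockSize
  df <- data.frame(v = med, r = br / nr, c = bc / nc)
  fit <- stats::lm(v ~ r + c + I(r^2) + I(c^2) + I(r * c), data = df)
  grid <- expand.grid(r = (seq_len(nr) - 0.5) / nr, c = (seq_len(nc) - 0.5) / nc)
  field <- matrix(stats::predict(fit, grid), nr, nc)
  field <- pmax(field, 1e-6)
  field / mean(field)
}

#' Suppress unstained background
#'
#' Sets all pixels with intensity strictly below \code{floor} to zero,
#' removing diffuse/unspecific background staining.
#'
#' @param image [CoreImage-class] or matrix.
#' @param floor 8-bit level; default 25.
#' @return A [CoreImage-class].
#' @export
suppressBackground <- function(image, floor = 25) {
  px <- .asPixelMatrix(image)
  px[px < floor] <- 0L
  coreImage(px, pixelSize = if (is(image, "CoreImage")) pixelSize(image) else NA_real_)
}

#' Median smoothing
#'
#' Replaces each pixel by the median of its square neighbourhood (replicated
#' borders). Default is the 3x3 kernel used ahead of binarization.
#'
#' @param image [CoreImage-class] or matrix.
#' @param kernelSide odd kernel edge length.
#' @return A [CoreImage-class].
#' @export
medianSmooth <- function(image, kernelSide = 3) {
  if (kernelSide %% 2 != 1) stop("kernelSide must be odd")
  px <- .asPixelMatrix(image)
  coreImage(.medianFilter(px, as.integer(kernelSide)),
            pixelSize = if (is(image, "CoreImage")) pixelSize(image) else NA_real_)
}

#' Otsu threshold of an 8-bit image
#'
#' Exhaustively maximizes the between-class variance over the 256-bin
#' histogram; returns the smallest maximizing level \code{t} (foreground is
#' \code{>= t}).
#'
#' @param image [CoreImage-class], matrix, or integer vector of values.
#' @param ignoreZero when \code{TRUE}, zero-valued (background) pixels are
#'   excluded from the histogram.
#' @return integer threshold in \code{[1, 255]}.
#' @export
otsuThreshold <- function(image, ignoreZero = FALSE) {
  v <- if (is(image, "CoreImage")) pixels(image) else image
  v <- as.integer(v)
  if (ignoreZero) v <- v[v != 0L]
  .otsuFromValues(v)
}

#' Binarize by Otsu's method
#'
#' @param image [CoreImage-class] or matrix.
#' @param ignoreZero exclude zero pixels from the histogram (used after
#'   background suppression, where zeros are not tissue).
#' @return logical mask matrix; \code{TRUE} where intensity \code{>=} the Otsu
#'   threshold.
#' @export
binarizeOtsu <- function(image, ignoreZero = FALSE) {
  px <- .asPixelMatrix(image)
  t <- otsuThreshold(px, ignoreZero = ignoreZero)
  px >= t
}

#' Remove small mask objects
#'
#' Deletes 8-connected components with area strictly below \code{minArea}
#' (smaller than a connective-tissue nucleus).
#'
#' @param mask logical or 0/1 matrix.
#' @param minArea minimum surviving component area in pixels; default 150.
#' @return logical mask.
#' @export
removeSmallObjects <- function(mask, minArea = 150) {
  m <- .asMaskMatrix(mask)
  lab <- .labelComponents(m)
  if (max(lab) == 0L) return(m)
  areas <- .labelAreas(lab)
  keep <- which(areas >= minArea)
  matrix(lab %in% keep, nrow(m), ncol(m)) & m
}

#' Remove isolated nuclei
#'
#' For each mask component, the bounding box is expanded by \code{margin} px
#' per side (clipped at the borders); if the expanded box contains no other
#' component the object is deleted — a lone nucleus with no neighbours is
#' assumed to be non-tumorous debris/connective tissue and excluded.
#'
#' @param mask logical or 0/1 matrix.
#' @param margin box expansion in pixels per side; default 20.
#' @return logical mask.
#' @export
removeIsolatedNuclei <- function(mask, margin = 20) {
  m <- .asMaskMatrix(mask)
  lab <- .labelComponents(m)
  k <- max(lab)
  if (k == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  idx <- which(lab > 0L, arr.ind = TRUE)
  ids <- lab[lab > 0L]
  rmin <- tapply(idx[, 1], ids, min); rmax <- tapply(idx[, 1], ids, max)
  cmin <- tapply(idx[, 2], ids, min); cmax <- tapply(idx[, 2], ids, max)
  drop <- logical(k)
  for (i in seq_len(k)) {
    key <- as.character(i)
    r0 <- max(1L, rmin[[key]] - margin); r1 <- min(nr, rmax[[key]] + margin)
    c0 <- max(1L, cmin[[key]] - margin); c1 <- min(nc, cmax[[key]] + margin)
    inbox <- lab[r0:r1, c0:c1]
    others <- unique(inbox[inbox > 0L])
    if (length(others) == 1L) drop[i] <- TRUE
  }
  out <- m
  if (any(drop)) out[lab %in% which(drop)] <- FALSE
  out
}

#' Remove large overstained (saturated) areas
#'
#' Connected regions of the mask whose pixels sit at the saturation level and
#' whose area reaches \code{minBlobArea} are removed: such blobs come from
#' agglomerated nuclei or excessive exposure and carry no usable structure.
#'
#' @param image [CoreImage-class] or matrix (intensities).
#' @param mask logical or 0/1 matrix.
#' @param saturationLevel 8-bit saturation level; default 255.
#' @param minBlobArea minimum blob area (px) to trigger removal; default 2000.
#' @return logical mask.
#' @export
removeOverstained <- function(image, mask, saturationLevel = 255, minBlobArea = 2000) {
  px <- .asPixelMatrix(image)
  m <- .asMaskMatrix(mask)
  sat <- m & px >= saturationLevel
  if (!any(sat)) return(m)
  lab <- .labelComponents(sat)
  areas <- .labelAreas(lab)
  big <- which(areas >= minBlobArea)
  if (!length(big)) return(m)
  out <- m
  out[lab %in% big] <- FALSE
  out
}

#' Morphological mask cleanup
#'
#' Optional opening-then-closing with a small diamond structuring element to
#' remove protrusions and fill pinholes left by binarization.
#'
#' @param mask logical matrix.
#' @param radius structuring-element radius; default 1.
#' @return logical mask.
#' @export
cleanupMask <- function(mask, radius = 1) {
  m <- matrix(as.numeric(.asMaskMatrix(mask)), nrow(mask), ncol(mask))
  br <- EBImage::makeBrush(2L * radius + 1L, shape = "diamond")
  out <- EBImage::closing(EBImage::opening(m, br), br)
  matrix(as.vector(out) > 0.5, nrow(mask), ncol(mask))
}

#' Full preprocessing pipeline for one core
#'
#' Runs, in order: shading correction, background suppression (floor),
#' median smoothing, Otsu binarization (ignoring zeros), small-object removal,
#' morphological cleanup, isolated-nucleus removal, overstained-area removal,
#' and a final small-object pass to drop rims left around removed saturated
#' blobs.
#'
#' @param image a [CoreImage-class].
#' @param config a [pipelineConfig()] list.
#' @param background optional flat-field; when \code{NULL} and the image
#'   carries a calibration field that field is used, otherwise the field is
#'   estimated.
#' @return list with \code{corrected} (shading-corrected [CoreImage-class],
#'   the reference image for all intensity statistics), \code{smoothed},
#'   \code{mask} (logical), and \code{log} (named counts per step).
#' @export
preprocessCore <- function(image, config = pipelineConfig(), background = NULL) {
  if (is.null(background) && is(image, "CoreImage") && length(calibration(image))) {
    background <- calibration(image)
  }
  corrected <- shadingCorrect(image, background, floor = config$floor)
  floored <- suppressBackground(corrected, floor = config$floor)
  smoothed <- medianSmooth(floored, kernelSide = config$medianKernel)
  mask <- binarizeOtsu(smoothed, ignoreZero = FALSE)
  log <- c(after_otsu = max(.labelComponents(mask)))
  mask <- removeSmallObjects(mask, minArea = config$minArea)
  log <- c(log, after_small = max(.labelComponents(mask)))
  if (isTRUE(config$cleanup)) {
    mask <- cleanupMask(mask, radius = config$cleanupRadius)
    mask <- removeSmallObjects(mask, minArea = config$minArea)
    log <- c(log, after_cleanup = max(.labelComponents(mask)))
  }
  if (isTRUE(config$removeIsolated)) {
    mask <- removeIsolatedNuclei(mask, margin = config$isolationMargin)
    log <- c(log, after_isolated = max(.labelComponents(mask)))
  }
  mask <- removeOverstained(smoothed, mask,
                            saturationLevel = config$saturationLevel,
                            minBlobArea = config$minBlobArea)
  mask <- removeSmallObjects(mask, minArea = config$minArea)
  log <- c(log, final = max(.labelComponents(mask)))
  list(corrected = corrected, smoothed = smoothed, mask = mask, log = log)
}
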