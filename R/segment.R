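#' Split nucleus pixels into bright and dark populations
#'
#' Intensity variation between nuclei (dark tumor vs brighter connective
#' tissue) causes over-segmentation when all nuclei are flooded together, so
#' the masked pixels are partitioned at an Otsu threshold (computed over
#' masked pixels only, ignoring background) and each population is segmented
#' separately.
#'
#' @param image [CoreImage-class] or matrix.
#' @param mask logical nucleus mask.
#' @return list with \code{bright} and \code{dark} ([CoreImage-class]s keeping
#'   only their population's pixels, zero elsewhere; together they tile the
#'   masked image and never overlap) and \code{threshold} (the Otsu level, or
#'   \code{NA} for an empty/constant mask).
#' @export
splitByBrightness <- function(image, mask) {
  px <- .asPixelMatrix(image)
  m <- .asMaskMatrix(mask)
  zero <- matrix(0L, nrow(px), ncol(px))
  if (!any(m)) {
    return(list(bright = coreImage(zero), dark = coreImage(zero), threshold = NA_real_))
  }
  vals <- px[m]
  if (length(unique(vals)) < 2) {
    warning("constant masked region: assigning all pixels to the dark population")
    dk <- zero; dk[m] <- px[m]
    return(list(bright = coreImage(zero), dark = coreImage(dk), threshold = NA_real_))
  }
  t <- .otsuFromValues(vals)
  br <- zero; dk <- zero
  selb <- m & px >= t
  seld <- m & px < t
  br[selb] <- px[selb]
  dk[seld] <- px[seld]
  list(bright = coreImage(br), dark = coreImage(dk), threshold = t)
}

#' Watershed seeds from the h-maxima transform
#'
#' Suppresses regional maxima of height < \code{h}, then labels the surviving
#' regional maxima; these plateaus are the seeds of the watershed. A constant
#' image yields a single seed region covering it (degenerate case, documented).
#'
#' @param image [CoreImage-class] or numeric matrix.
#' @param h peak height to survive suppression, in 8-bit levels (>= 1).
#' @param mask optional logical mask; seeds are only sought inside it.
#' @return integer label matrix of seed regions.
#' @export
hMaximaSeeds <- function(image, h, mask = NULL) {
  if (h < 1) stop("h must be >= 1")
  px <- .asPixelMatrix(image)
  storage.mode(px) <- "double"
  if (!is.null(mask)) {
    mask <- .asMaskMatrix(mask)
    if (!any(mask)) return(matrix(0L, nrow(px), ncol(px)))
    lo <- min(px[mask]) - h - 1
    px[!mask] <- lo
  }
  hm <- .hMaximaTransform(px, h)
  rmax <- .regionalMaxima(hm, mask)
  .labelComponents(rmax)
}

#' Seeded watershed segmentation
#'
#' Grows basins from the given seed regions over the intensity landscape until
#' every masked pixel belongs to exactly one seed; realized with
#' EBImage's Voronoi-based seeded region growing (\code{propagate}), which is
#' deterministic. Mask components containing no seed are left unlabeled
#' (callers add fallback seeds; see [segmentNuclei()]).
#'
#' @param image [CoreImage-class] or matrix guiding the flooding.
#' @param seeds integer label matrix of seed regions.
#' @param mask logical mask restricting the flooding.
#' @return integer label matrix; label count equals seed count.
#' @export
seededWatershed <- function(image, seeds, mask) {
  px <- .asPixelMatrix(image)
  m <- .asMaskMatrix(mask)
  if (max(seeds) == 0L) stop("seeded watershed requires at least one seed")
  seeds <- seeds * (m * 1L)   # seeds outside the mask cannot grow
  out <- EBImage::propagate(px / 255, seeds, mask = m)
  matrix(as.integer(out), nrow(px), ncol(px))
}

#' Segment nuclei of one core
#'
#' Composite segmentation: brightness split, h-maxima seeding and seeded
#' watershed independently on the bright and dark populations, label merging,
#' small-fragment removal, and per-nucleus statistics. Statistics are computed
#' from \code{image} (the shading-corrected, pre-median image); seeding and
#' flooding use \code{smoothed} (median-filtered) to keep noise peaks from
#' spawning seeds.
#'
#' @param image [CoreImage-class]: the shading-corrected intensity reference.
#' @param mask logical nucleus mask from [preprocessCore()].
#' @param h h-maxima height (8-bit levels); default 10.
#' @param smoothed optional [CoreImage-class] used for seeding/flooding;
#'   defaults to \code{medianSmooth(image)}.
#' @param minSegmentArea segments smaller than this after watershed are
#'   dropped (slivers from the brightness split); default 150.
#' @return A [NucleusSet-class].
#' @export
segmentNuclei <- function(image, mask, h = 10, smoothed = NULL, minSegmentArea = 150) {
  px <- .asPixelMatrix(image)
  m <- .asMaskMatrix(mask)
  nr <- nrow(px); nc <- ncol(px)
  if (!any(m)) {
    return(nucleusSet(matrix(0L, nr, nc), .emptyNucleusTable()))
  }
  if (is.null(smoothed)) smoothed <- medianSmooth(image)
  spx <- .asPixelMatrix(smoothed)
  parts <- splitByBrightness(spx, m)
  labAll <- matrix(0L, nr, nc)
  offset <- 0L
  for (part in list(parts$dark, parts$bright)) {
    pm <- pixels(part) > 0 & m
    if (!any(pm)) next
    seeds <- hMaximaSeeds(spx, h, mask = pm)
    seeds <- .ensureSeedPerComponent(seeds, spx, pm)
    lab <- seededWatershed(spx, seeds, pm)
    lab[lab > 0L] <- lab[lab > 0L] + offset
    labAll[lab > 0L] <- lab[lab > 0L]
    offset <- max(labAll)
  }
  # drop sliver segments, relabel contiguously
  areas <- .labelAreas(labAll)
  if (length(areas)) {
    small <- which(areas < minSegmentArea)
    if (length(small)) labAll[labAll %in% small] <- 0L
  }
  labAll <- .relabel(labAll)
  nucleusSet(labAll, computeNucleusStats(labAll, px))
}

# give every mask component at least one seed (fallback: its brightest pixel,
# first in scan order on ties)
.ensureSeedPerComponent <- function(seeds, px, mask) {
  comp <- .labelComponents(mask)
  k <- max(comp)
  if (k == 0L) return(seeds)
  seeded <- unique(comp[seeds > 0L])
  missing <- setdiff(seq_len(k), seeded)
  if (length(missing)) {
    nxt <- max(seeds)
    for (cid in missing) {
      idx <- which(comp == cid)
      best <- idx[which.max(px[idx])]
      nxt <- nxt + 1L
      seeds[best] <- nxt
    }
  }
  seeds
}

.relabel <- function(lab) {
  present <- sort(unique(lab[lab > 0L]))
  if (!length(present)) return(lab)
  remap <- integer(max(present))
  remap[present] <- seq_along(present)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

.nucleusCols <- c("label", "area", "centroid_row", "centroid_col",
                  "bbox_min_row", "bbox_min_col", "bbox_max_row", "bbox_max_col",
                  "mean_intensity", "min_intensity", "max_intensity",
                  "median_intensity", "std_intensity", "major_axis",
                  "minor_axis", "eccentricity", "equivalent_diameter",
                  "extent", "perimeter")

.emptyNucleusTable <- function() {
  df <- as.data.frame(setNames(rep(list(numeric(0)), length(.nucleusCols)), .nucleusCols))
  df$label <- integer(0)
  df
}

#' Per-nucleus shape and intensity statistics
#'
#' Computes, for every label of a label image, the per-cell quantities used as
#' node features and by the single-cell rules: area, centroid, bounding box,
#' intensity statistics (mean/min/max/median/sd over the nucleus's own pixels),
#' ellipse-equivalent axes (same normalized second central moments as the pixel
#' set), eccentricity \eqn{\sqrt{1-(x_{min}/x_{max})^2}}, equivalent diameter
#' \eqn{\sqrt{4A/\pi}}, extent (area / bounding-box area) and perimeter
#' (oriented boundary trace with diagonal steps weighted \eqn{\sqrt{2}}).
#'
#' @param labels integer label matrix.
#' @param image [CoreImage-class] or matrix supplying intensities.
#' @return data.frame, one row per label (see [NucleusSet-class]).
#' @export
computeNucleusStats <- function(labels, image) {
  px <- .asPixelMatrix(image)
  k <- max(labels)
  if (k == 0L) return(.emptyNucleusTable())
  idx <- which(labels > 0L)
  lab <- labels[idx]
  vals <- as.numeric(px[idx])
  nr <- nrow(labels)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  ids <- seq_len(k)
  n <- tabulate(lab, nbins = k)
  sr <- rowsum(as.numeric(rows), lab)[, 1]
  sc <- rowsum(as.numeric(cols), lab)[, 1]
  srr <- rowsum(rows^2, lab)[, 1]
  scc <- rowsum(cols^2, lab)[, 1]
  src <- rowsum(rows * cols, lab)[, 1]
  sv <- rowsum(vals, lab)[, 1]
  svv <- rowsum(vals^2, lab)[, 1]
  cr <- sr / n; cc <- sc / n
  mu <- sv / n
  varv <- (svv - n * mu^2) / pmax(n - 1, 1)
  sdev <- sqrt(pmax(varv, 0))
  byLab <- split(seq_along(lab), lab)
  medv <- vapply(byLab, function(i) stats::median(vals[i]), numeric(1))
  minv <- vapply(byLab, function(i) min(vals[i]), numeric(1))
  maxv <- vapply(byLab, function(i) max(vals[i]), numeric(1))
  rmin <- vapply(byLab, function(i) min(rows[i]), numeric(1))
  rmax <- vapply(byLab, function(i) max(rows[i]), numeric(1))
  cmin <- vapply(byLab, function(i) min(cols[i]), numeric(1))
  cmax <- vapply(byLab, function(i) max(cols[i]), numeric(1))
  # ellipse-equivalent axes (Matlab regionprops convention: + 1/12 per axis)
  mrr <- srr / n - cr^2 + 1 / 12
  mcc <- scc / n - cc^2 + 1 / 12
  mrc <- src / n - cr * cc
  common <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
  major <- 4 * sqrt((mrr + mcc + common) / 2)
  minor <- 4 * sqrt(pmax((mrr + mcc - common) / 2, 0))
  ecc <- sqrt(pmax(1 - (minor / major)^2, 0))
  perim <- vapply(ids, function(id) {
    i <- byLab[[as.character(id)]]
    .objectPerimeter(labels, id, coords = cbind(rows[i], cols[i]))
  }, numeric(1))
  data.frame(
    label = ids, area = as.numeric(n),
    centroid_row = cr, centroid_col = cc,
    bbox_min_row = rmin, bbox_min_col = cmin,
    bbox_max_row = rmax, bbox_max_col = cmax,
    mean_intensity = mu, min_intensity = minv, max_intensity = maxv,
    median_intensity = medv, std_intensity = sdev,
    major_axis = major, minor_axis = minor, eccentricity = ecc,
    equivalent_diameter = sqrt(4 * n / pi),
    extent = n / ((rmax - rmin + 1) * (cmax - cmin + 1)),
    perimeter = perim,
    row.names = NULL
  )
}

#' Segmentation accuracy report
#'
#' Builds the correct / over-segmented / under-segmented trichotomy with
#' percentages from raw counts.
#'
#' @param total number of ground-truth nuclei.
#' @param correct one-to-one matches.
#' @param overSegmented truth nuclei split across several segments.
#' @param underSegmented truth nuclei merged into a shared segment (or missed).
#' @return object of class \code{SegmentationReport}: a list with the four
#'   counts and \code{pct_correct}, \code{pct_over}, \code{pct_under}.
#' @examples
#' r <- segmentationReport(100, 94, 5, 1)
#' r$pct_correct
#' @export
segmentationReport <- function(total, correct, overSegmented, underSegmented) {
  stopifnot(correct + overSegmented + underSegmented == total)
  structure(list(
    total = total, correct = correct,
    over_segmented = overSegmented, under_segmented = underSegmented,
    pct_correct = 100 * correct / total,
    pct_over = 100 * overSegmented / total,
    pct_under = 100 * underSegmented / total
  ), class = "SegmentationReport")
}

#' @export
print.SegmentationReport <- function(x, ...) {
  cat(sprintf("Segmentation of %d nuclei: %.1f%% correct, %.1f%% over-, %.1f%% under-segmented\n",
              x$total, x$pct_correct, x$pct_over, x$pct_under))
  invisible(x)
}

#' Evaluate a segmentation against ground truth
#'
#' Matches result labels to truth nuclei by majority pixel overlap. A truth
#' nucleus is \emph{over-segmented} when two or more result labels lie
#' majority-inside it; truth nuclei are \emph{under-segmented} when a single
#' result label majority-covers two or more of them; a one-to-one mutual
#' majority match is \emph{correct}. Truth nuclei matched to nothing (missed)
#' are counted under-segmented so the trichotomy sums to the total.
#'
#' @param result [NucleusSet-class] or integer label matrix.
#' @param truth [GroundTruth-class] or integer label matrix.
#' @return A \code{SegmentationReport} (see [segmentationReport()]).
#' @export
evaluateSegmentation <- function(result, truth) {
  rl <- if (is(result, "NucleusSet")) labelImage(result) else result
  tl <- if (is(truth, "GroundTruth")) labelImage(truth) else truth
  if (!identical(dim(rl), dim(tl))) stop("result and truth dimensions differ")
  nt <- max(tl)
  if (nt == 0L) stop("ground truth contains no nuclei")
  areaR <- .labelAreas(rl)
  areaT <- .labelAreas(tl)
  both <- rl > 0L & tl > 0L
  correct <- 0L; over <- 0L; under <- 0L
  if (any(both)) {
    r <- rl[both]; t <- tl[both]
    code <- (as.numeric(r) - 1) * nt + as.numeric(t)
    ov <- rowsum(rep(1, length(code)), code)
    codes <- as.numeric(rownames(ov))
    ovr <- as.integer((codes - 1) %/% nt + 1)   # result label
    ovt <- as.integer((codes - 1) %% nt + 1)    # truth label
    ovn <- ov[, 1]
    coversT <- ovn > 0.5 * areaT[ovt]           # result majority-covers truth
    insideT <- ovn > 0.5 * areaR[ovr]           # result majority-inside truth
    # under-segmentation: a result label majority-covering >= 2 truth nuclei
    coveredCount <- tabulate(ovr[coversT], nbins = max(rl))
    mergers <- which(coveredCount >= 2L)
    underSet <- unique(ovt[coversT & ovr %in% mergers])
    # over-segmentation: >= 2 result labels majority-inside one truth nucleus
    insideCount <- tabulate(ovt[insideT], nbins = nt)
    overSet <- setdiff(which(insideCount >= 2L), underSet)
    # correct: mutual majority one-to-one
    mutual <- unique(ovt[coversT & insideT])
    correctSet <- setdiff(mutual, c(underSet, overSet))
    correct <- length(correctSet)
    over <- length(overSet)
    under <- nt - correct - over
  } else {
    under <- nt
  }
  segmentationReport(nt, correct, over, under)
}
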