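# Internal image primitives shared across modules. All matrices are indexed
# [row, col], 0-based pixel coordinates never leave this file.

# shift a matrix by (dr, dc), padding with `fill`
.shiftMat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# 3x3 grayscale dilation (8-neighbourhood maximum), -Inf border
.dilate3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- pmax(out, .shiftMat(m, dr, dc, -Inf))
  }
  out
}

# Morphological grayscale reconstruction by dilation of `marker` under
# `maskimg` (8-connectivity); hybrid sweep + queue algorithm in C++.
.reconstructDilate <- function(marker, maskimg) {
  storage.mode(marker) <- "double"
  storage.mode(maskimg) <- "double"
  .reconstructDilateCpp(marker, maskimg)
}

# Regional maxima of an integer-valued image restricted to `mask` (logical);
# returns logical matrix. Uses the reconstruction characterisation
# rmax(f) = f - R_f(f - 1) > 0, computed only where mask is TRUE.
.regionalMaxima <- function(img, mask = NULL) {
  work <- img
  if (!is.null(mask)) work[!mask] <- -1
  rec <- .reconstructDilate(work - 1, work)
  rm <- (work - rec) > 0
  if (!is.null(mask)) rm <- rm & mask
  rm
}

# h-maxima transform: suppress maxima of height < h
.hMaximaTransform <- function(img, h) {
  .reconstructDilate(img - h, img)
}

# Otsu threshold on an 8-bit histogram. `counts` has 256 entries for levels
# 0..255. Returns the smallest level t maximizing between-class variance for
# the split {< t} vs {>= t}. Errors when fewer than two levels are populated.
.otsuFromCounts <- function(counts) {
  stopifnot(length(counts) == 256)
  levs <- 0:255
  if (sum(counts > 0) < 2) {
    stop("Otsu threshold undefined: need >= 2 distinct intensity levels")
  }
  counts <- as.numeric(counts)
  n <- sum(counts)
  w0 <- cumsum(counts)                      # pixels with level <= k
  s0 <- cumsum(counts * levs)
  total <- s0[256]
  # candidate thresholds t = 1..255 split into {<= t-1} and {>= t}
  w0k <- w0[1:255]; s0k <- s0[1:255]
  w1k <- n - w0k
  valid <- w0k > 0 & w1k > 0
  mu0 <- s0k / w0k
  mu1 <- (total - s0k) / w1k
  sigma <- w0k * w1k * (mu0 - mu1)^2
  sigma[!valid] <- -Inf
  which.max(sigma)                          # index k corresponds to t = k
}

# Otsu threshold from raw integer values in [0,255]
.otsuFromValues <- function(values) {
  .otsuFromCounts(tabulate(as.integer(values) + 1L, nbins = 256))
}

# 8-connected component labeling. EBImage::bwlabel is 4-connected; merge labels
# that touch diagonally with a union-find pass, then relabel 1..K contiguously
# in order of first (column-major) appearance.
.labelComponents <- function(mask, connectivity = 8L) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  k <- max(lab)
  if (k == 0L) return(lab)
  if (connectivity == 8L && k > 1L) {
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
    for (d in list(c(1L, 1L), c(1L, -1L))) {
      sh <- .shiftMat(lab, d[1], d[2], 0L)
      sel <- lab > 0L & sh > 0L & lab != sh
      if (any(sel)) {
        prs <- unique(cbind(lab[sel], sh[sel]))
        for (i in seq_len(nrow(prs))) unite(prs[i, 1], prs[i, 2])
      }
    }
    root <- vapply(seq_len(k), find, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  # contiguous relabeling, deterministic scan order
  present <- unique(lab[lab > 0L])
  if (length(present)) {
    remap <- integer(max(present))
    firstpos <- vapply(present, function(l) which(lab == l)[1], numeric(1))
    ord <- present[order(firstpos)]
    remap[ord] <- seq_along(ord)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

# Areas of each label in a label image: vector indexed by label id
.labelAreas <- function(lab) {
  k <- max(lab)
  if (k == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins = k)
}

# Exact median filter with replicated borders; odd square kernel.
# Row-sort trick: gather the k^2 shifted copies and take the middle order
# statistic of each pixel's neighbourhood with a single global order().
.medianFilter <- function(img, kernelSide) {
  stopifnot(kernelSide %% 2 == 1)
  r <- (kernelSide - 1L) / 2L
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0, nr + 2 * r, nc + 2 * r)
  pad[(r + 1):(r + nr), (r + 1):(r + nc)] <- img
  # replicate borders
  if (r > 0) {
    pad[1:r, ] <- pad[rep(r + 1, r), ]
    pad[(r + nr + 1):(r + nr + r), ] <- pad[rep(r + nr, r), ]
    pad[, 1:r] <- pad[, rep(r + 1, r)]
    pad[, (r + nc + 1):(r + nc + r)] <- pad[, rep(r + nc, r)]
  }
  k2 <- kernelSide^2
  n <- nr * nc
  neigh <- matrix(0, n, k2)
  j <- 1L
  for (dc in -r:r) for (dr in -r:r) {
    neigh[, j] <- as.vector(pad[(r + 1 + dr):(r + nr + dr), (r + 1 + dc):(r + nc + dc)])
    j <- j + 1L
  }
  sorted <- matrix(neigh[order(row(neigh), neigh)], nrow = n, byrow = TRUE)
  matrix(sorted[, (k2 + 1L) / 2L], nr, nc)
}

# Pixel coordinates (row, col) of one label in a label image
.labelPixels <- function(lab, id) {
  which(lab == id, arr.ind = TRUE)
}

# Boundary pixels of a pixel set within its label image (pixels with a
# 4-neighbour outside the set); cheap pruning for pairwise distance queries.
.boundaryPixels <- function(coords, lab, id) {
  nr <- nrow(lab); nc <- ncol(lab)
  onb <- rep(FALSE, nrow(coords))
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    rr <- coords[, 1] + d[1]; cc <- coords[, 2] + d[2]
    outside <- rr < 1 | rr > nr | cc < 1 | cc > nc
    inb <- !outside
    nbv <- rep(0L, nrow(coords))
    nbv[inb] <- lab[cbind(rr[inb], cc[inb])]
    onb <- onb | outside | nbv != id
  }
  coords[onb, , drop = FALSE]
}

# Perimeter of one object: oriented contour trace with diagonal steps weighted
# sqrt(2). Falls back to 4 - area-proportional for degenerate 1-2 px objects.
.objectPerimeter <- function(lab, id, coords = NULL) {
  if (is.null(coords)) coords <- .labelPixels(lab, id)
  if (nrow(coords) == 1L) return(4)       # unit square boundary
  r0 <- min(coords[, 1]); r1 <- max(coords[, 1])
  c0 <- min(coords[, 2]); c1 <- max(coords[, 2])
  crop <- matrix(0L, r1 - r0 + 3L, c1 - c0 + 3L)
  crop[cbind(coords[, 1] - r0 + 2L, coords[, 2] - c0 + 2L)] <- 1L
  oc <- EBImage::ocontour(crop)[[1]]
  if (nrow(oc) < 2L) return(4)
  d <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

# Ellipse-equivalent axes from normalized second central moments, Matlab
# regionprops convention (adds 1/12 for the unit-square pixel footprint).
.ellipseAxes <- function(coords) {
  r <- coords[, 1]; c <- coords[, 2]
  mrr <- mean((r - mean(r))^2) + 1 / 12
  mcc <- mean((c - mean(c))^2) + 1 / 12
  mrc <- mean((r - mean(r)) * (c - mean(c)))
  common <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
  l1 <- (mrr + mcc + common) / 2
  l2 <- (mrr + mcc - common) / 2
  c(major = 4 * sqrt(l1), minor = 4 * sqrt(max(l2, 0)))
}

.asPixelMatrix <- function(x) {
  if (is(x, "CoreImage")) pixels(x) else x
}

.asMaskMatrix <- function(x) {
  m <- if (is(x, "CoreImage")) pixels(x) else x
  m != 0
}
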