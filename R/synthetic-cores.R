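#' Specification of a synthetic DAPI core
#'
#' Defines the scene statistics of a simulated tissue-microarray core: dark,
#' mutually touching tumor nuclei in clusters; brighter, sparser stromal
#' nuclei (elongated fibroblast-like, small bright round lymphocyte-like, and
#' generic connective-tissue nuclei) arranged in loose strands; a smooth
#' multiplicative shading field; saturated overstained blobs; additive
#' Gaussian noise. The defaults are the package's reference conditions for
#' its synthetic benchmarks.
#'
#' Within-cluster tumor nearest-neighbour pixel gaps are kept at 1-4 px (so
#' the diamond-radius-2 touching rule links them); gaps between tumor and
#' stroma, and between distinct clusters/strands, are kept above 4 px. A
#' fraction \code{fractionStromaConnected} of stroma strands also have
#' within-strand gaps of 1-4 px (forming small stroma subgraphs, as loose
#' connective strands do); the remaining strands have gaps of 6-16 px — never
#' touching, but close enough to survive the isolated-nucleus filter.
#'
#' @param imageHeight,imageWidth image size in pixels.
#' @param coreRadius radius of the circular core footprint in pixels.
#' @param nTumorClusters number of tumor nests.
#' @param tumorNucleiPerCluster nuclei per nest.
#' @param tumorMeanIntensity,stromaMeanIntensity 8-bit class mean levels;
#'   tumor must be darker than stroma.
#' @param nStromaNuclei total stromal nuclei.
#' @param fractionFibroblast,fractionLymphocyte subtype proportions among
#'   stromal nuclei (the remainder is generic); must sum to <= 1.
#' @param fractionStromaConnected fraction of stroma strands rendered with
#'   touching (1-4 px) gaps.
#' @param shadingAmplitude relative amplitude of the multiplicative shading
#'   field, in \code{[0, 1]}.
#' @param noiseSd additive Gaussian noise standard deviation (8-bit levels).
#' @param nOverstainedBlobs number of saturated (level 255) blobs.
#' @param rngSeed integer seed; the entire core is a deterministic function
#'   of the spec including this seed.
#' @return list of class \code{SyntheticCoreSpec}.
#' @export
syntheticCoreSpec <- function(imageHeight = 512, imageWidth = 512,
                              coreRadius = 230,
                              nTumorClusters = 6, tumorNucleiPerCluster = 8,
                              tumorMeanIntensity = 85, stromaMeanIntensity = 150,
                              nStromaNuclei = 40,
                              fractionFibroblast = 0.25,
                              fractionLymphocyte = 0.25,
                              fractionStromaConnected = 0.5,
                              shadingAmplitude = 0.10, noiseSd = 5,
                              nOverstainedBlobs = 1, rngSeed = 1) {
  spec <- list(imageHeight = imageHeight, imageWidth = imageWidth,
               coreRadius = coreRadius, nTumorClusters = nTumorClusters,
               tumorNucleiPerCluster = tumorNucleiPerCluster,
               tumorMeanIntensity = tumorMeanIntensity,
               stromaMeanIntensity = stromaMeanIntensity,
               nStromaNuclei = nStromaNuclei,
               fractionFibroblast = fractionFibroblast,
               fractionLymphocyte = fractionLymphocyte,
               fractionStromaConnected = fractionStromaConnected,
               shadingAmplitude = shadingAmplitude, noiseSd = noiseSd,
               nOverstainedBlobs = nOverstainedBlobs, rngSeed = rngSeed)
  counts <- c(spec$nTumorClusters, spec$tumorNucleiPerCluster,
              spec$nStromaNuclei, spec$nOverstainedBlobs)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (spec$tumorMeanIntensity >= spec$stromaMeanIntensity) {
    stop("tumor nuclei must be darker than stromal nuclei")
  }
  props <- c(spec$fractionFibroblast, spec$fractionLymphocyte,
             spec$fractionStromaConnected, spec$shadingAmplitude)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (spec$fractionFibroblast + spec$fractionLymphocyte > 1) {
    stop("fractionFibroblast + fractionLymphocyte must be <= 1")
  }
  if (spec$noiseSd < 0) stop("noiseSd must be >= 0")
  structure(spec, class = "SyntheticCoreSpec")
}

# rasterize a rotated filled ellipse; returns coords (row, col) and the
# normalized squared ellipse radius q in [0, 1] per pixel
.rasterEllipse <- function(cr, cc, a, b, theta, nr, nc) {
  ext <- ceiling(max(a, b)) + 1L
  r0 <- max(1L, floor(cr - ext)); r1 <- min(nr, ceiling(cr + ext))
  c0 <- max(1L, floor(cc - ext)); c1 <- min(nc, ceiling(cc + ext))
  if (r0 > r1 || c0 > c1) return(NULL)
  g <- expand.grid(r = r0:r1, c = c0:c1)
  dr <- g$r - cr; dc <- g$c - cc
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  q <- u^2 + v^2
  inside <- q <= 1
  if (!any(inside)) return(NULL)
  list(coords = cbind(g$r[inside], g$c[inside]), q = q[inside])
}

# minimum L1 gap from `coords` to each existing label within window `w`;
# returns list(overlap = logical, gaps = named numeric vector)
.minGapToLabels <- function(L, coords, w = 16L) {
  nr <- nrow(L); nc <- ncol(L)
  if (any(L[coords] > 0L)) return(list(overlap = TRUE, gaps = numeric(0)))
  r0 <- max(1L, min(coords[, 1]) - w); r1 <- min(nr, max(coords[, 1]) + w)
  c0 <- max(1L, min(coords[, 2]) - w); c1 <- min(nc, max(coords[, 2]) + w)
  win <- L[r0:r1, c0:c1]
  labs <- unique(win[win > 0L])
  if (!length(labs)) return(list(overlap = FALSE, gaps = numeric(0)))
  gaps <- vapply(labs, function(l) {
    idx <- which(win == l, arr.ind = TRUE)
    idx[, 1] <- idx[, 1] + r0 - 1L; idx[, 2] <- idx[, 2] + c0 - 1L
    min(abs(outer(coords[, 1], idx[, 1], "-")) + abs(outer(coords[, 2], idx[, 2], "-")))
  }, numeric(1))
  list(overlap = FALSE, gaps = setNames(gaps, labs))
}

# effective radius of a rotated ellipse along absolute direction phi
.ellipseRadiusAlong <- function(a, b, theta, phi) {
  a * b / sqrt((b * cos(phi - theta))^2 + (a * sin(phi - theta))^2)
}

#' Generate a synthetic core with ground truth
#'
#' Renders the scene described by a [syntheticCoreSpec()]: nuclei are filled
#' rotated ellipses with a radial intensity dome (brightest at the centroid)
#' around a per-nucleus base level drawn from the class mean; the scene is
#' modulated by a smooth multiplicative shading field, Gaussian noise is
#' added, and overstained blobs are burned in at level 255. Identical specs
#' (including \code{rngSeed}) produce bit-identical output.
#'
#' @param spec a [syntheticCoreSpec()].
#' @return list with \code{image} (a [CoreImage-class]; its
#'   \code{calibration} slot carries the true shading field, standing in for
#'   a flat-field calibration exposure) and \code{truth}
#'   (a [GroundTruth-class] captured before noise).
#' @export
generateCore <- function(spec) {
  stopifnot(inherits(spec, "SyntheticCoreSpec"))
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(spec$rngSeed)

  nr <- spec$imageHeight; nc <- spec$imageWidth
  ctr <- c(nr, nc) / 2
  L <- matrix(0L, nr, nc)
  qimg <- matrix(0, nr, nc)          # ellipse dome coordinate per nucleus pixel
  base <- numeric(0)                 # per-nucleus base intensity
  cls <- character(0); sub <- character(0)
  clusterOf <- integer(0)
  maxTries <- 800L

  inCore <- function(cr, cc, slack = 0) {
    sqrt((cr - ctr[1])^2 + (cc - ctr[2])^2) <= spec$coreRadius - slack
  }
  addNucleus <- function(coords, q, b, klass, subtype, clus) {
    id <- length(base) + 1L
    L[coords] <<- id
    qimg[coords] <<- q
    base[id] <<- b
    cls[id] <<- klass; sub[id] <<- subtype
    clusterOf[id] <<- clus
    id
  }
  drawShape <- function(subtype) {
    switch(subtype,
      tumor      = c(a = max(12, rnorm(1, 16, 1.5)), b = max(10, rnorm(1, 13, 1.2))),
      fibroblast = c(a = max(16, rnorm(1, 21, 2.0)), b = max(3.5, rnorm(1, 4.5, 0.5))),
      lymphocyte = { r <- max(7.2, rnorm(1, 8, 0.5)); c(a = r, b = r) },
      generic_stroma = c(a = max(9, rnorm(1, 12, 1.0)), b = max(8, rnorm(1, 10, 1.0)))
    )
  }
  drawBase <- function(subtype) {
    m <- switch(subtype,
      tumor = spec$tumorMeanIntensity,
      lymphocyte = min(spec$stromaMeanIntensity + 60, 235),
      spec$stromaMeanIntensity)
    s <- if (subtype == "lymphocyte") 5 else 6
    max(30, min(245, rnorm(1, m, s)))
  }

  # place one nucleus at gap `gapRange` from anchor nucleus `anchorId`,
  # keeping >= clearGap from every other existing nucleus
  placeNear <- function(anchorId, subtype, gapRange, clearGap, clus, klass) {
    anchor <- which(L == anchorId, arr.ind = TRUE)
    acr <- mean(anchor[, 1]); acc <- mean(anchor[, 2])
    for (try in seq_len(maxTries)) {
      sh <- drawShape(subtype)
      th <- runif(1, 0, pi)
      phi <- runif(1, 0, 2 * pi)
      target <- runif(1, gapRange[1], gapRange[2])
      # anchor's extent along phi, estimated from its raster
      aext <- max(abs((anchor[, 1] - acr) * cos(phi) + (anchor[, 2] - acc) * sin(phi)))
      d <- aext + .ellipseRadiusAlong(sh["a"], sh["b"], th, phi + pi) + target
      ok <- FALSE
      for (adj in 1:6) {
        cr <- acr + d * cos(phi); cc <- acc + d * sin(phi)
        if (!inCore(cr, cc, slack = max(sh) + 2)) break
        e <- .rasterEllipse(cr, cc, sh["a"], sh["b"], th, nr, nc)
        if (is.null(e)) break
        g <- .minGapToLabels(L, e$coords)
        if (g$overlap) { d <- d + 2; next }
        aGap <- if (as.character(anchorId) %in% names(g$gaps))
          g$gaps[[as.character(anchorId)]] else Inf
        sameClus <- names(g$gaps)[clusterOf[as.integer(names(g$gaps))] == clus]
        others <- setdiff(names(g$gaps), sameClus)
        if (length(others) && min(g$gaps[others]) < clearGap) break
        if (!is.finite(aGap)) { d <- d - 4; next }
        if (aGap > gapRange[2]) { d <- d - (aGap - target); next }
        if (aGap < gapRange[1]) { d <- d + (gapRange[1] - aGap) + 0.5; next }
        if (length(sameClus) && min(g$gaps[sameClus]) < 1) { d <- d + 1; next }
        addNucleus(e$coords, e$q, drawBase(subtype), klass, subtype, clus)
        ok <- TRUE
        break
      }
      if (ok) return(TRUE)
    }
    FALSE
  }
  placeSeedNucleus <- function(subtype, clus, klass, clearFromAll) {
    for (try in seq_len(maxTries)) {
      sh <- drawShape(subtype)
      th <- runif(1, 0, pi)
      rad <- spec$coreRadius - max(sh) - 10
      ang <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * rad
      cr <- ctr[1] + rr * cos(ang); cc <- ctr[2] + rr * sin(ang)
      e <- .rasterEllipse(cr, cc, sh["a"], sh["b"], th, nr, nc)
      if (is.null(e)) next
      g <- .minGapToLabels(L, e$coords, w = 16L)
      if (g$overlap || (length(g$gaps) && min(g$gaps) < clearFromAll)) next
      return(addNucleus(e$coords, e$q, drawBase(subtype), klass, subtype, clus))
    }
    NA_integer_
  }

  # ---- overstained blobs first (nuclei then keep clear of them) ------------
  nBlob <- spec$nOverstainedBlobs
  if (nBlob > 0) {
    for (bID in seq_len(nBlob)) {
      done <- FALSE
      for (try in seq_len(maxTries)) {
        rad <- runif(1, 27, 33)
        ang <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * (spec$coreRadius - rad - 10)
        cr <- ctr[1] + rr * cos(ang); cc <- ctr[2] + rr * sin(ang)
        e <- .rasterEllipse(cr, cc, rad, rad, 0, nr, nc)
        if (is.null(e)) next
        g <- .minGapToLabels(L, e$coords, w = 12L)
        if (g$overlap || (length(g$gaps) && min(g$gaps) < 10)) next
        addNucleus(e$coords, e$q, 255, "blob", "blob", -1L)
        done <- TRUE
        break
      }
      if (!done) stop("core over-packed: no room for overstained blob")
    }
  }

  # ---- tumor clusters -------------------------------------------------------
  clusterCenters <- matrix(numeric(0), 0, 2)
  clusId <- 0L
  # nests must not fuse: keep centres apart in proportion to nest size
  minClusterSep <- 20 + 26 * sqrt(max(spec$tumorNucleiPerCluster, 1))
  if (spec$nTumorClusters > 0 && spec$tumorNucleiPerCluster > 0) {
    for (k in seq_len(spec$nTumorClusters)) {
      clusId <- clusId + 1L
      completed <- FALSE
      for (attempt in 1:6) {
        # snapshot so a stuck cluster can be torn down and replaced
        snap <- list(L = L, qimg = qimg, base = base, cls = cls, sub = sub,
                     clusterOf = clusterOf, centers = clusterCenters)
        placed <- NA_integer_
        for (try in seq_len(maxTries)) {
          ang <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * (spec$coreRadius - 60)
          cr <- ctr[1] + rr * cos(ang); cc <- ctr[2] + rr * sin(ang)
          if (nrow(clusterCenters) &&
              min(sqrt((clusterCenters[, 1] - cr)^2 + (clusterCenters[, 2] - cc)^2)) < minClusterSep) next
          sh <- drawShape("tumor"); th <- runif(1, 0, pi)
          e <- .rasterEllipse(cr, cc, sh["a"], sh["b"], th, nr, nc)
          if (is.null(e)) next
          g <- .minGapToLabels(L, e$coords)
          if (g$overlap || (length(g$gaps) && min(g$gaps) < 8)) next
          placed <- addNucleus(e$coords, e$q, drawBase("tumor"), "tumor", "tumor", clusId)
          clusterCenters <- rbind(clusterCenters, c(cr, cc))
          break
        }
        if (is.na(placed)) stop("core over-packed: could not place tumor cluster ", k)
        members <- placed
        while (length(members) < spec$tumorNucleiPerCluster) {
          anchor <- members[sample.int(length(members), 1)]
          if (placeNear(anchor, "tumor", c(1, 4), clearGap = 6, clus = clusId,
                        klass = "tumor")) {
            members <- c(members, length(base))
          } else break
        }
        if (length(members) == spec$tumorNucleiPerCluster) { completed <- TRUE; break }
        L <- snap$L; qimg <- snap$qimg; base <- snap$base; cls <- snap$cls
        sub <- snap$sub; clusterOf <- snap$clusterOf; clusterCenters <- snap$centers
      }
      if (!completed) stop("core over-packed: could not complete tumor cluster ", k)
    }
  }

  # ---- stroma strands -------------------------------------------------------
  if (spec$nStromaNuclei > 0) {
    remaining <- spec$nStromaNuclei
    nFib <- round(spec$fractionFibroblast * spec$nStromaNuclei)
    nLym <- round(spec$fractionLymphocyte * spec$nStromaNuclei)
    pool <- c(rep("fibroblast", nFib), rep("lymphocyte", nLym),
              rep("generic_stroma", spec$nStromaNuclei - nFib - nLym))
    pool <- sample(pool)
    while (remaining > 0) {
      clusId <- clusId + 1L
      size <- min(remaining, sample(2:4, 1))
      connected <- runif(1) < spec$fractionStromaConnected
      gapRange <- if (connected) c(1, 4) else c(7, 15)
      seedId <- placeSeedNucleus(pool[1], clusId, "stroma", clearFromAll = 8)
      if (is.na(seedId)) stop("core over-packed: could not place stromal nucleus")
      pool <- pool[-1]; remaining <- remaining - 1
      members <- seedId
      while (length(members) < size && remaining > 0) {
        anchor <- members[length(members)]
        if (placeNear(anchor, pool[1], gapRange, clearGap = 6, clus = clusId,
                      klass = "stroma")) {
          members <- c(members, length(base))
          pool <- pool[-1]; remaining <- remaining - 1
        } else break
      }
    }
  }

  # ---- strip blob pseudo-labels from the scene ------------------------------
  blobIdx <- integer(0)
  if (nBlob > 0) {
    blobIdx <- which(L > 0L & L <= nBlob)
    L[blobIdx] <- 0L
    L[L > 0L] <- L[L > 0L] - nBlob
    qimg[blobIdx] <- 0
    base <- base[-seq_len(nBlob)]; cls <- cls[-seq_len(nBlob)]
    sub <- sub[-seq_len(nBlob)]; clusterOf <- clusterOf[-seq_len(nBlob)]
  }

  # ---- ground truth (pre-noise) --------------------------------------------
  ids <- seq_along(base)
  tmask <- matrix(FALSE, nr, nc)
  if (any(cls == "tumor")) {
    tum <- matrix(0, nr, nc)
    sel <- L > 0L
    tum[sel] <- as.numeric(cls[L[sel]] == "tumor")
    br <- EBImage::makeBrush(25L, shape = "disc")
    tmask <- matrix(as.vector(EBImage::dilate(tum, br)) > 0.5, nr, nc)
  }
  truth <- groundTruth(L,
                       classes = setNames(cls, ids),
                       subtypes = setNames(sub, ids),
                       tumorMask = tmask)

  # ---- rendering ------------------------------------------------------------
  img <- matrix(10, nr, nc)                       # faint unstained background
  nz <- which(L > 0L)
  img[nz] <- base[L[nz]] * (0.85 + 0.30 * (1 - qimg[nz]))
  # smooth multiplicative shading: tilted plane + broad Gaussian bump
  rn <- (row(img) / nr) - 0.5; cn <- (col(img) / nc) - 0.5
  cf <- runif(3, -1, 1)
  bumpC <- runif(2, 0.25, 0.75)
  s <- cf[1] * rn + cf[2] * cn +
    cf[3] * exp(-((rn + 0.5 - bumpC[1])^2 + (cn + 0.5 - bumpC[2])^2) / (2 * 0.35^2))
  if (max(abs(s)) > 0) s <- s / max(abs(s))
  field <- 1 + spec$shadingAmplitude * s
  img <- img * field
  if (spec$noiseSd > 0) img <- img + rnorm(length(img), 0, spec$noiseSd)
  img <- pmin(pmax(round(img), 0), 255)
  img[blobIdx] <- 255                             # saturated overstained areas
  storage.mode(img) <- "integer"
  list(image = coreImage(img, pixelSize = 0.46, calibration = field),
       truth = truth)
}
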