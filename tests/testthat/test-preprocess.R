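test_that("shading correction removes a known flat-field and rejects degenerate input", {
  # flat field leaves a constant image unchanged
  img <- coreImage(matrix(100L, 16, 16))
  expect_equal(pixels(shadingCorrect(img, matrix(1, 16, 16))),
               matrix(100L, 16, 16))
  # forward-simulate a linear ramp (mean 1), correct with it, recover pattern
  n <- 64
  ramp <- matrix(rep(seq(0.8, 1.2, length.out = n), each = n), n, n)
  ramp <- ramp / mean(ramp)
  pattern <- matrix(0L, n, n); pattern[20:40, 20:40] <- 120L
  shaded <- coreImage(pmin(round(pattern * ramp), 255))
  rec <- shadingCorrect(shaded, ramp)
  expect_lte(max(abs(pixels(rec)[20:40, 20:40] - 120)), 1)
  expect_error(shadingCorrect(img, matrix(0, 16, 16)), "degenerate")
})

test_that("background suppression floors at the stated threshold (strict <)", {
  img <- coreImage(matrix(c(24L, 25L, 26L, 0L), 2, 2))
  out <- pixels(suppressBackground(img, floor = 25))
  expect_equal(as.vector(out), c(0L, 25L, 26L, 0L))
  expect_equal(pixels(suppressBackground(coreImage(matrix(0L, 4, 4)))),
               matrix(0L, 4, 4))
  expect_equal(pixels(suppressBackground(coreImage(matrix(200L, 4, 4)))),
               matrix(200L, 4, 4))
})

test_that("median smoothing matches the order-statistic definition", {
  expect_equal(pixels(medianSmooth(coreImage(matrix(70L, 9, 9)))),
               matrix(70L, 9, 9))
  # single bright outlier in a zero image vanishes
  z <- matrix(0L, 9, 9); z[5, 5] <- 200L
  expect_equal(pixels(medianSmooth(coreImage(z))), matrix(0L, 9, 9))
  # 3x3 patch: centre becomes the sorted middle of the nine values
  p <- matrix(c(10L, 40L, 70L, 20L, 50L, 80L, 30L, 60L, 90L), 3, 3)
  expect_equal(pixels(medianSmooth(coreImage(p)))[2, 2], 50)
  expect_error(medianSmooth(coreImage(p), kernelSide = 4), "odd")
})

test_that("Otsu threshold maximizes between-class variance (brute-force oracle)", {
  # perfectly bimodal image: the bright half is foreground
  img <- matrix(50L, 20, 20); img[, 11:20] <- 200L
  mask <- binarizeOtsu(img)
  expect_equal(mask, col(img) >= 11)
  set.seed(42)
  for (i in 1:20) {
    v <- as.integer(sample(0:255, 400, replace = TRUE,
                           prob = runif(256)^3))
    if (length(unique(v)) < 2) next
    expect_equal(otsuThreshold(v), oracleOtsu(v))
  }
  # ignoreZero restricts the histogram to nonzero levels
  v <- c(rep(0L, 500), rep(60L, 100), rep(200L, 100))
  expect_equal(otsuThreshold(v, ignoreZero = TRUE), oracleOtsu(c(rep(60L, 100), rep(200L, 100))))
  expect_error(otsuThreshold(rep(7L, 100)), "distinct")
})

test_that("small-object removal keeps the 150 px boundary and matches a labeling oracle", {
  m2 <- matrix(FALSE, 60, 200)
  m2[2:11, 2:11] <- TRUE                            # 100
  m2[21:35, 31:40] <- TRUE                          # 150
  m2[41:50, 61:100] <- TRUE                         # 400
  m2[5:15, 150:161] <- TRUE; m2[5, 162] <- TRUE     # 133
  out <- removeSmallObjects(m2, minArea = 150)
  areas <- c(100, 150, 400, 133)
  expect_equal(sum(out), sum(areas[areas >= 150]))
  expect_equal(removeSmallObjects(matrix(FALSE, 10, 10)), matrix(FALSE, 10, 10))
})

test_that("isolated-nucleus removal follows the expanded-bounding-box rule", {
  # one lone nucleus far from everything: removed
  m <- matrix(FALSE, 100, 100)
  m[45:55, 45:55] <- TRUE
  expect_equal(sum(removeIsolatedNuclei(m, margin = 20)), 0)
  # two nuclei 10 px apart: each sees the other in its expanded box, kept
  m2 <- matrix(FALSE, 100, 100)
  m2[40:50, 20:30] <- TRUE
  m2[40:50, 41:51] <- TRUE
  expect_equal(removeIsolatedNuclei(m2, margin = 20), m2)
  expect_equal(removeIsolatedNuclei(matrix(FALSE, 5, 5)), matrix(FALSE, 5, 5))
})

test_that("overstained removal deletes only large saturated blobs", {
  img <- matrix(100L, 120, 120)
  mask <- matrix(FALSE, 120, 120)
  mask[10:80, 10:80] <- TRUE
  # a 50x50 saturated blob (2500 px >= 2000) inside the mask: removed
  img2 <- img; img2[21:70, 21:70] <- 255L
  out <- removeOverstained(img2, mask, minBlobArea = 2000)
  expect_equal(sum(out), sum(mask) - 2500)
  # no saturated pixels: mask unchanged
  expect_equal(removeOverstained(img, mask, minBlobArea = 2000), mask)
  # saturated blob below the area cut: kept
  img3 <- img; img3[10:30, 10:30] <- 255L   # 441 px
  expect_equal(removeOverstained(img3, mask, minBlobArea = 2000), mask)
})

test_that("mask cleanup filters are idempotent and dimension-preserving", {
  set.seed(7)
  m <- matrix(runif(64 * 64) < 0.4, 64, 64)
  for (f in list(function(x) removeSmallObjects(x, 20),
                 function(x) removeIsolatedNuclei(x, 10),
                 cleanupMask)) {
    once <- f(m)
    expect_identical(dim(once), dim(m))
    expect_equal(f(once), once)
    expect_lte(sum(once), sum(m) + 8)   # closing may fill pinholes slightly
  }
})
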