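bump2 <- function(h1 = 100, h2 = 100, sep = 20, width = 40) {
  # two Gaussian bumps on a 30 x 60 grid; valley depth controlled by sep/width
  g <- expand.grid(r = 1:30, c = 1:60)
  b <- h1 * exp(-((g$r - 15)^2 + (g$c - 30 + sep / 2)^2) / width) +
       h2 * exp(-((g$r - 15)^2 + (g$c - 30 - sep / 2)^2) / width)
  matrix(as.integer(round(b)), 30, 60)
}

test_that("brightness split partitions masked pixels at the Otsu level", {
  img <- matrix(0L, 40, 50)
  img[5:24, 5:24] <- 60L
  img[5:24, 26:45] <- 200L
  mask <- img > 0
  sp <- splitByBrightness(img, mask)
  expect_equal(sum(pixels(sp$dark) == 60), 400)
  expect_equal(sum(pixels(sp$bright) == 200), 400)
  # partition property on random images: disjoint, union covers the mask
  set.seed(11)
  for (i in 1:10) {
    ri <- matrix(as.integer(sample(0:255, 900, TRUE)), 30, 30)
    rm <- matrix(runif(900) < 0.5, 30, 30)
    if (length(unique(ri[rm])) < 2) next
    sp <- splitByBrightness(ri, rm)
    b <- pixels(sp$bright) > 0; d <- pixels(sp$dark) > 0
    expect_false(any(b & d))
    covered <- b | d
    expect_true(all(covered[rm & ri > 0]))
  }
  e <- splitByBrightness(img, matrix(FALSE, 40, 50))
  expect_equal(sum(pixels(e$bright)) + sum(pixels(e$dark)), 0)
})

test_that("h-maxima seeding suppresses shallow peaks and is monotone in h", {
  # valley between equal bumps: survives low h, merges at high h
  img <- bump2()
  valley <- img[15, 30]; peak <- max(img)
  depth <- peak - valley
  expect_gt(depth, 30)   # fixture sanity: designed valley depth ~ 50
  expect_equal(max(hMaximaSeeds(img, h = 30)), 2)
  expect_equal(max(hMaximaSeeds(img, h = depth + 10)), 1)
  # single bump: one seed for any h below its height
  one <- bump2(h2 = 0)
  expect_equal(max(hMaximaSeeds(one, h = 30)), 1)
  # degenerate constant image: a single plateau seed (documented convention)
  expect_equal(max(hMaximaSeeds(matrix(42L, 12, 12), h = 5)), 1)
  expect_error(hMaximaSeeds(img, h = 0), "h must be")
  # monotonicity over a realistic synthetic core
  core <- generateCore(tinySpec(3))
  pre <- preprocessCore(core$image)
  counts <- vapply(c(4, 8, 16, 32, 64), function(h) {
    max(hMaximaSeeds(pixels(pre$smoothed), h, mask = pre$mask))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("seeded watershed assigns every masked pixel to exactly one seed", {
  # disjoint blobs, one seed each
  img <- matrix(0L, 30, 60)
  img[10:20, 10:20] <- 100L; img[10:20, 40:50] <- 100L
  mask <- img > 0
  seeds <- matrix(0L, 30, 60); seeds[15, 15] <- 1L; seeds[15, 45] <- 2L
  w <- seededWatershed(img, seeds, mask)
  expect_true(all(w[10:20, 10:20] == 1L))
  expect_true(all(w[10:20, 40:50] == 2L))
  expect_true(all(w[!mask] == 0L))
  # two touching equal bumps with two seeds split along the midline valley
  img2 <- bump2()
  mask2 <- img2 > 10
  seeds2 <- matrix(0L, 30, 60); seeds2[15, 20] <- 1L; seeds2[15, 40] <- 2L
  w2 <- seededWatershed(img2, seeds2, mask2)
  expect_true(all(w2[mask2] > 0L))
  split1 <- max(which(w2[15, ] == 1L)); split2 <- min(which(w2[15, ] == 2L))
  expect_equal(split2, split1 + 1L)
  expect_lte(abs(split1 - 30), 2)       # boundary at the valley (col ~30)
  expect_error(seededWatershed(img2, matrix(0L, 30, 60), mask2), "seed")
})

test_that("segmentNuclei recovers nuclei of both brightness populations", {
  core <- generateCore(tinySpec(4))
  pre <- preprocessCore(core$image)
  nuc <- segmentNuclei(pre$corrected, pre$mask, h = 10, smoothed = pre$smoothed)
  df <- nuclei(nuc)
  expect_s4_class(nuc, "NucleusSet")
  expect_gt(nrow(df), 0)
  # label partition: pixel sets disjoint by construction of a label image;
  # every nucleus meets the validity invariants (validity ran at creation)
  expect_true(validObject(nuc))
  # empty mask gives an empty set
  e <- segmentNuclei(pre$corrected, matrix(FALSE, 384, 384))
  expect_equal(nrow(nuclei(e)), 0)
  # both dark (tumor) and bright (stroma) populations are represented
  truthCls <- nucleusClasses(core$truth)
  expect_gt(sum(df$mean_intensity < 120), 0)
  expect_gt(sum(df$mean_intensity > 120), 0)
})

test_that("per-nucleus statistics match closed forms on known shapes", {
  # perfect disc: eccentricity ~ 0, equivalent diameter from area
  L <- shapeMask(10, 10)
  st <- computeNucleusStats(L, matrix(150L, 48, 48))
  expect_lt(st$eccentricity, 0.1)
  expect_equal(st$equivalent_diameter, sqrt(4 * st$area / pi))
  # axis-aligned filled rectangle: extent exactly 1
  R <- matrix(0L, 20, 20); R[5:14, 3:12] <- 1L
  str <- computeNucleusStats(R, matrix(100L, 20, 20))
  expect_equal(str$extent, 1.0)
  expect_equal(str$area, 100)
  # area 100 example of the closed form
  expect_equal(str$equivalent_diameter, sqrt(400 / pi), tolerance = 1e-12)
  # intensity statistics over the nucleus's own pixels
  img <- matrix(0L, 20, 20); img[5:14, 3:12] <- as.integer(1:100)
  sti <- computeNucleusStats(R, img)
  expect_equal(sti$mean_intensity, mean(1:100))
  expect_equal(sti$median_intensity, median(1:100))
  expect_equal(sti$std_intensity, sd(1:100))
  expect_equal(sti$min_intensity, 1)
  expect_equal(sti$max_intensity, 100)
})

test_that("segmentation evaluation implements the over/under trichotomy", {
  truthL <- matrix(0L, 40, 40)
  truthL[5:14, 5:14] <- 1L
  truthL[25:34, 5:14] <- 2L
  truthL[5:14, 25:34] <- 3L
  # identical result: 100% correct
  r <- evaluateSegmentation(truthL, truthL)
  expect_equal(r$pct_correct, 100)
  expect_equal(r$correct + r$over_segmented + r$under_segmented, r$total)
  # nucleus 1 split in two: one over-segmented
  split <- truthL
  split[5:14, 5:9] <- 4L
  r2 <- evaluateSegmentation(split, truthL)
  expect_equal(r2$over_segmented, 1)
  expect_equal(r2$correct, 2)
  # nuclei 1 and 2 merged into one label: both under-segmented
  merged <- truthL
  merged[25:34, 5:14] <- 1L
  merged[15:24, 5:14] <- 1L   # bridge so the merger covers both
  r3 <- evaluateSegmentation(merged, truthL)
  expect_equal(r3$under_segmented, 2)
  expect_equal(r3$correct, 1)
  expect_error(evaluateSegmentation(truthL[1:20, ], truthL), "dimension")
})

test_that("report percentages are consistent for arbitrary counts", {
  set.seed(5)
  for (i in 1:25) {
    parts <- as.vector(stats::rmultinom(1, size = sample(50:5000, 1), prob = c(0.9, 0.07, 0.03)))
    rp <- segmentationReport(sum(parts), parts[1], parts[2], parts[3])
    expect_equal(rp$pct_correct + rp$pct_over + rp$pct_under, 100)
  }
})
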