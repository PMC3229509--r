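test_that("min-max normalization, clipping and the denormalization inverse", {
  out <- normalizeFeatures(data.frame(a = c(2, 4, 6)))
  expect_equal(out$x$a, c(0, 0.5, 1))
  # test values beyond the training bounds are clipped
  clipped <- normalizeFeatures(data.frame(a = c(1, 7)), bounds = out$bounds)
  expect_equal(clipped$x$a, c(0, 1))
  # round trip for in-range data
  set.seed(2)
  x <- data.frame(a = runif(20, 2, 6), b = runif(20, -5, 5))
  nn <- normalizeFeatures(x)
  back <- denormalizeFeatures(nn$x, nn$bounds)
  expect_equal(back$a, x$a, tolerance = 1e-12)
  expect_equal(back$b, x$b, tolerance = 1e-12)
  expect_warning(normalizeFeatures(data.frame(a = c(1, 2), b = c(3, 3))), "constant")
  expect_error(normalizeFeatures(data.frame(a = c(3, 3))), "constant")
})

test_that("F-score reproduces hand-computed values and degenerate conventions", {
  # tumor {0,0,1,1} vs stroma {2,2,3,3}: numerator 2, denominator 2/3
  x <- c(0, 0, 1, 1, 2, 2, 3, 3)
  y <- c(1, 1, 1, 1, -1, -1, -1, -1)
  expect_equal(fScore(x, y), 3.0)
  # class means equal to the overall mean: zero
  expect_equal(fScore(c(1, 2, 1, 2), c(1, 1, -1, -1)), 0)
  # both classes constant: infinite discrimination if means differ
  expect_equal(fScore(c(5, 5, 9, 9), c(1, 1, -1, -1)), Inf)
  expect_equal(fScore(c(5, 5, 5, 5), c(1, 1, -1, -1)), 0)
  # wider separation at fixed variance increases the score
  f1 <- fScore(c(0, 1, 4, 5), c(1, 1, -1, -1))
  f2 <- fScore(c(0, 1, 8, 9), c(1, 1, -1, -1))
  expect_gt(f2, f1)
  # affine rescaling of the column leaves the score unchanged
  set.seed(3)
  v <- rnorm(40); lab <- rep(c(1, -1), 20)
  expect_equal(fScore(3.7 * v - 11, lab), fScore(v, lab), tolerance = 1e-9)
  expect_error(fScore(c(1, 2, 3), c(1, 1, 1)), "labels|class")
})

test_that("F-score ranking finds planted informative features", {
  set.seed(4)
  n <- 120
  lab <- rep(c("tumor", "stroma"), each = n / 2)
  x <- as.data.frame(matrix(rnorm(n * 22), n, 22))
  names(x) <- names(featureCategories())
  informative <- c("avg_area", "avg_std_intensity", "diameter")
  for (f in informative) x[[f]] <- x[[f]] + ifelse(lab == "tumor", 2.5, 0)
  rk <- rankAndSelect(x, lab, k = 3)
  expect_setequal(rk$selected, informative)
  expect_equal(rk$ranking$feature[1:3], rk$selected)
  expect_true(all(diff(rk$ranking$f_score) <= 1e-12))
  # k = all features selects everything
  expect_length(rankAndSelect(x, lab, k = 22)$selected, 22)
  expect_error(rankAndSelect(x, lab, k = 0), "positive")
  expect_error(rankAndSelect(x, lab, k = 23), "exceeds")
  # permuted labels carry (almost) no signal
  rkp <- rankAndSelect(x, sample(lab), k = 3)
  expect_lt(max(rkp$ranking$f_score), 0.5)
})

test_that("RBF-SVM separates linear and nonlinear patterns deterministically", {
  set.seed(5)
  # linearly separable blobs: perfect training accuracy
  x <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2), matrix(rnorm(100, 2, 0.3), 50, 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("tumor", "stroma"), each = 50)
  m <- trainTissueSVM(x, y)
  expect_equal(mean(svmPredict(m, x) == y), 1.0)
  # agreement with the fitting library's own predictions
  fit <- e1071::svm(x, factor(y, levels = c("stroma", "tumor")),
                    type = "C-classification", kernel = "radial",
                    cost = 1, gamma = 1 / 2, scale = FALSE)
  expect_equal(svmPredict(m, x), as.character(predict(fit, x)))
  # XOR pattern: not linearly separable, RBF handles it
  xx <- cbind(rep(c(0, 0, 1, 1), 30) + rnorm(120, 0, 0.08),
              rep(c(0, 1, 0, 1), 30) + rnorm(120, 0, 0.08))
  colnames(xx) <- c("f1", "f2")
  yy <- ifelse(xor(round(xx[, 1]) > 0.5, round(xx[, 2]) > 0.5), "tumor", "stroma")
  mx <- trainTissueSVM(xx, yy, C = 10, gamma = 2)
  expect_gt(mean(svmPredict(mx, xx) == yy), 0.95)
  # swapping the class labels flips every prediction
  ySwap <- ifelse(y == "tumor", "stroma", "tumor")
  mSwap <- trainTissueSVM(x, ySwap)
  expect_true(all(svmPredict(mSwap, x) != svmPredict(m, x)))
  # determinism
  expect_identical(trainTissueSVM(x, y)$coefs, m$coefs)
  expect_error(trainTissueSVM(x, rep("tumor", 100)), "both classes")
})

test_that("subgraph truth labels follow the centroid majority with stroma ties", {
  mask <- matrix(FALSE, 50, 50); mask[1:50, 1:25] <- TRUE
  mkGraph <- function(cols) {
    nodes <- data.frame(label = seq_along(cols),
                        centroid_row = 25, centroid_col = cols)
    cellGraph(nodes, cbind(seq_len(length(cols) - 1), 2:length(cols)))
  }
  expect_equal(assignTruthLabel(mkGraph(c(5, 10, 15)), mask), "tumor")
  expect_equal(assignTruthLabel(mkGraph(c(5, 10, 30, 35, 40)), mask), "stroma")
  expect_equal(assignTruthLabel(mkGraph(c(5, 10, 30, 35)), mask), "stroma")  # tie
})

test_that("classification report computes per-core and aggregate accuracies", {
  # perfect prediction
  p <- rep(c("tumor", "stroma"), 10)
  r <- evaluateClassification(p, p, rep(1, 20))
  expect_equal(r$per_core$overall, 100)
  expect_equal(r$pooled_overall, 100)
  # 8/10 tumor and 6/10 stroma correct: overall 70, producer's 80 / 60
  truth <- rep(c("tumor", "stroma"), each = 10)
  pred <- truth
  pred[9:10] <- "stroma"; pred[11:14] <- "tumor"
  r2 <- evaluateClassification(pred, truth, rep(1, 20))
  expect_equal(r2$per_core$overall, 70)
  expect_equal(r2$per_core$tumor_producers, 80)
  expect_equal(r2$per_core$stroma_producers, 60)
  # aggregate over two cores at 80% and 90%: mean 85, two-point sd
  t2 <- rep("tumor", 20)
  p2 <- t2; p2[1:2] <- "stroma"; p2[11] <- "stroma"
  r3 <- evaluateClassification(p2, t2, rep(c("a", "b"), each = 10))
  agg <- r3$aggregate[r3$aggregate$metric == "overall", ]
  expect_equal(agg$mean, 85)
  expect_equal(agg$sd, sd(c(80, 90)))
  # a core without stroma nuclei is excluded from the stroma aggregate
  expect_equal(r3$aggregate$mean[r3$aggregate$metric == "stroma_producers"], NaN)
})

test_that("model serialization round-trips predictions exactly", {
  set.seed(6)
  cores <- lapply(1:2, function(s) generateCore(tinySpec(s)))
  cl <- trainTissueClassifier(lapply(cores, `[[`, "image"),
                              lapply(cores, `[[`, "truth"))
  test <- generateCore(tinySpec(99))
  r1 <- classifyCore(test$image, cl)
  path <- tempfile(fileext = ".json")
  writeTissueClassifier(cl, path)
  cl2 <- readTissueClassifier(path)
  expect_equal(cl2@selectedFeatures, cl@selectedFeatures)
  r2 <- classifyCore(test$image, cl2)
  expect_identical(r1$perNucleus, r2$perNucleus)
  # deterministic: same model, same input, same labels
  r3 <- classifyCore(test$image, cl)
  expect_identical(r1$perNucleus, r3$perNucleus)
})
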