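path3 <- edgeListGraph(cbind(c(1L, 2L), c(2L, 3L)), 3)

test_that("eccentricity, diameter, radius and central points on hand graphs", {
  expect_equal(graphEccentricities(path3), c("1" = 2L, "2" = 1L, "3" = 2L))
  k4 <- edgeListGraph(t(combn(4L, 2)), 4)
  expect_true(all(graphEccentricities(k4) == 1L))
  expect_equal(diameterRadiusCentral(path3),
               c(diameter = 2, radius = 1, n_central = 1))
  c5 <- edgeListGraph(cbind(1:5, c(2:5, 1L)), 5)
  expect_equal(diameterRadiusCentral(c5),
               c(diameter = 2, radius = 2, n_central = 5))
  k2 <- edgeListGraph(cbind(1L, 2L), 2)
  expect_equal(diameterRadiusCentral(k2),
               c(diameter = 1, radius = 1, n_central = 2))
  expect_error(graphEccentricities(edgeListGraph(cbind(1L, 2L), 3)), "connected")
})

test_that("clustering coefficient and end-node statistics on hand graphs", {
  tri <- edgeListGraph(cbind(c(1L, 1L, 2L), c(2L, 3L, 3L)), 3)
  expect_equal(avgClusteringCoefficient(tri), 1.0)
  star <- edgeListGraph(cbind(1L, 2:5), 5)
  expect_equal(avgClusteringCoefficient(star), 0.0)
  p5 <- edgeListGraph(cbind(1:4, 2:5), 5)
  expect_equal(endNodeStats(p5), c(n_end = 2, pct_end = 40))
  expect_equal(endNodeStats(edgeListGraph(cbind(1:5, c(2:5, 1L)), 5)),
               c(n_end = 0, pct_end = 0))
})

test_that("hop-plot values and exponent follow the log-log regression definition", {
  expect_equal(hopPlotValues(path3), c(2, 3))
  expect_equal(hopPlotExponent(path3), log(3 / 2) / log(2), tolerance = 1e-12)
  k4 <- edgeListGraph(t(combn(4L, 2)), 4)
  expect_warning(hp <- hopPlotExponent(k4), "degenerate")
  expect_equal(hp, 0)
})

test_that("graph metrics match brute-force BFS/triple oracles on random graphs", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    edges <- randomConnectedGraph(n, extra = sample(0:(2 * n), 1))
    g <- edgeListGraph(edges, n)
    d <- oracleDistances(graphEdges(g), n)
    eccO <- apply(d, 1, max)
    ecc <- graphEccentricities(g)
    expect_equal(unname(ecc[as.character(1:n)]), as.integer(eccO))
    drc <- diameterRadiusCentral(g)
    expect_equal(unname(drc["diameter"]), max(eccO))
    expect_equal(unname(drc["radius"]), min(eccO))
    expect_equal(unname(drc["n_central"]), sum(eccO == min(eccO)))
    expect_equal(avgClusteringCoefficient(g),
                 mean(oracleClustering(graphEdges(g), n)), tolerance = 1e-12)
    deg <- tabulate(as.integer(graphEdges(g)), nbins = n)
    expect_equal(unname(endNodeStats(g)["n_end"]), sum(deg == 1))
    # hop-plot accumulation against the BFS distance matrix
    dv <- d[upper.tri(d)]
    if (max(eccO) >= 2) {
      expect_equal(hopPlotValues(g),
                   vapply(1:max(eccO), function(h) sum(dv <= h), numeric(1)))
    }
    # structural invariants
    expect_lte(drc["radius"], drc["diameter"])
    expect_lte(drc["diameter"], 2 * drc["radius"])
  }
})

test_that("the 22-feature vector combines topology with averaged node features", {
  core <- generateCore(tinySpec(8))
  an <- analyzeCore(core$image)
  skipIf <- length(an$subgraphs) == 0
  expect_false(skipIf)   # the reference scene always yields subgraphs
  g <- an$subgraphs[[which.max(vapply(an$subgraphs, function(s) nrow(graphNodes(s)), numeric(1)))]]
  fv <- graphFeatureVector(g)
  expect_named(fv, names(featureCategories()))
  expect_true(all(is.finite(fv)))
  n <- nrow(graphNodes(g)); m <- nrow(graphEdges(g))
  expect_equal(unname(fv["avg_degree"]), 2 * m / n)
  expect_equal(unname(fv["avg_area"]), mean(graphNodes(g)$area))
  expect_equal(unname(fv["avg_mean_intensity"]), mean(graphNodes(g)$mean_intensity))
  # hop plot saturates at all unordered pairs
  if (fv["diameter"] >= 2) {
    p <- hopPlotValues(g)
    expect_true(all(diff(p) >= 0))
    expect_equal(p[length(p)], n * (n - 1) / 2)
  }
  # node order must not matter
  nodes <- graphNodes(g)
  g2 <- cellGraph(nodes[rev(seq_len(nrow(nodes))), ], graphEdges(g))
  expect_equal(graphFeatureVector(g2), fv)
  expect_error(graphFeatureVector(edgeListGraph(matrix(integer(0), 0, 2), 1)),
               ">= 2 nodes")
  # feature matrix binds one row per subgraph
  fm <- featureMatrix(an$subgraphs)
  expect_equal(nrow(fm), length(an$subgraphs))
  expect_true(all(is.finite(as.matrix(fm[, -1]))))
})
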