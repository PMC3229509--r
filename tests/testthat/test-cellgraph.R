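test_that("touching rule equals the diamond dilation-intersection definition", {
  # hand-placed pixel pairs at known L1 distances
  a <- cbind(10, 10)
  expect_true(nucleiTouch(a, cbind(12, 12), radius = 2))    # L1 = 4
  expect_false(nucleiTouch(a, cbind(12, 13), radius = 2))   # L1 = 5
  expect_true(nucleiTouch(a, cbind(10, 11), radius = 1))    # adjacent
  # oracle equivalence on random small masks
  set.seed(21)
  for (i in 1:200) {
    a <- unique(cbind(sample(1:12, 6, TRUE), sample(1:12, 6, TRUE)))
    b <- unique(cbind(sample(8:20, 6, TRUE), sample(8:20, 6, TRUE)))
    key <- paste(b[, 1], b[, 2]) %in% paste(a[, 1], a[, 2])
    b <- b[!key, , drop = FALSE]
    if (!nrow(b)) next
    r <- sample(1:3, 1)
    expect_equal(nucleiTouch(a, b, r), oracleTouching(a, b, r))
  }
})

test_that("intensity compatibility uses a strict 30-level difference", {
  expect_true(intensityCompatible(100, 129))
  expect_false(intensityCompatible(100, 130))
  expect_true(intensityCompatible(77, 77))
  expect_false(intensityCompatible(50, 120))
})

test_that("cell-graph construction links touching, intensity-compatible nuclei", {
  # scene: two close dark nuclei, one close bright nucleus, one distant nucleus
  L <- matrix(0L, 60, 80)
  L[20:29, 10:19] <- 1L
  L[20:29, 23:32] <- 2L     # gap 3 from nucleus 1 (touching)
  L[20:29, 36:45] <- 3L     # gap 3 from nucleus 2, but much brighter
  L[50:59, 60:69] <- 4L     # far from everything
  img <- matrix(0L, 60, 80)
  img[L == 1L] <- 100L; img[L == 2L] <- 110L; img[L == 3L] <- 200L; img[L == 4L] <- 105L
  ns <- nucleusSet(L, computeNucleusStats(L, img))
  g <- buildCellGraph(ns, radius = 2, threshold = 30)
  expect_equal(graphEdges(g), matrix(c(1L, 2L), 1))
  comp <- connectedSubgraphs(g)
  expect_length(comp$subgraphs, 1)
  expect_setequal(graphNodes(comp$subgraphs[[1]])$label, c(1, 2))
  expect_setequal(comp$isolated$label, c(3, 4))
  # empty input
  e <- buildCellGraph(nucleusSet(matrix(0L, 5, 5), computeNucleusStats(matrix(0L, 5, 5), matrix(0L, 5, 5))))
  expect_equal(nrow(graphEdges(e)), 0)
})

test_that("graph construction is invariant to node order and matches all pairs", {
  core <- generateCore(tinySpec(6))
  an <- analyzeCore(core$image)
  ns <- an$nuclei
  g <- buildCellGraph(ns, radius = 2, threshold = 30)
  # all-pairs oracle on the same nucleus set
  df <- nuclei(ns); L <- labelImage(ns)
  n <- nrow(df)
  oracleEdges <- matrix(integer(0), 0, 2)
  pxs <- lapply(df$label, function(id) which(L == id, arr.ind = TRUE))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(df$mean_intensity[i] - df$mean_intensity[j]) >= 30) next
    if (oracleTouching(pxs[[i]], pxs[[j]], 2)) {
      oracleEdges <- rbind(oracleEdges, c(df$label[i], df$label[j]))
    }
  }
  got <- graphEdges(g)
  expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
               oracleEdges[order(oracleEdges[, 1], oracleEdges[, 2]), , drop = FALSE],
               ignore_attr = TRUE)
  # permuting the node table leaves the edge set unchanged
  perm <- sample(nrow(df))
  ns2 <- nucleusSet(L, df[perm, ])
  g2 <- buildCellGraph(ns2, radius = 2, threshold = 30)
  expect_equal(graphEdges(g2), graphEdges(g))
})

test_that("subgraph decomposition matches a union-find oracle and partitions nodes", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(5:25, 1)
    edges <- randomConnectedGraph(n, extra = sample(0:n, 1))
    drop <- sample(nrow(edges), max(0, nrow(edges) - sample(3:(n + 3), 1)))
    if (length(drop)) edges <- edges[-drop, , drop = FALSE]
    g <- edgeListGraph(edges, n)
    comp <- connectedSubgraphs(g)
    memb <- oracleComponents(graphEdges(g), n)
    linked <- sort(unique(as.integer(graphEdges(g))))
    nontrivial <- unique(memb[linked])
    expect_length(comp$subgraphs, length(nontrivial))
    # every node is in exactly one subgraph or isolated
    all <- c(unlist(lapply(comp$subgraphs, function(s) graphNodes(s)$label)),
             comp$isolated$label)
    expect_setequal(all, seq_len(n))
    expect_equal(anyDuplicated(all), 0)
  }
  # path a-b-c plus isolated d
  g <- edgeListGraph(cbind(c(1L, 2L), c(2L, 3L)), 4)
  comp <- connectedSubgraphs(g)
  expect_length(comp$subgraphs, 1)
  expect_setequal(graphNodes(comp$subgraphs[[1]])$label, 1:3)
  expect_equal(comp$isolated$label, 4)
  # complete graph on 10 nodes stays whole
  k10 <- t(combn(10L, 2))
  expect_length(connectedSubgraphs(edgeListGraph(k10, 10))$subgraphs, 1)
})
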