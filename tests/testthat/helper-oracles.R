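# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths they verify (no igraph, no EBImage,
# no package-internal helpers).

# all-pairs shortest-path distances by repeated BFS over an edge list
oracleDistances <- function(edges, n) {
  adj <- vector("list", n)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s; dist <- 0
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) if (is.infinite(d[s, w])) {
          d[s, w] <- dist + 1; nxt <- c(nxt, w)
        }
      }
      frontier <- unique(nxt); dist <- dist + 1
    }
  }
  d
}

# local clustering coefficient by enumerating neighbour pairs
oracleClustering <- function(edges, n) {
  has <- matrix(FALSE, n, n)
  if (nrow(edges)) {
    has[edges] <- TRUE; has[edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  vapply(seq_len(n), function(i) {
    nb <- which(has[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    e <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (has[nb[a], nb[b]]) e <- e + 1
    }
    2 * e / (k * (k - 1))
  }, numeric(1))
}

# connected components via union-find
oracleComponents <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      ra <- find(edges[i, 1]); rb <- find(edges[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Eq.-style dilation-intersection touching test: build each pixel set's
# diamond dilation explicitly as an offset union, then intersect
oracleTouching <- function(a, b, radius) {
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[abs(offs$dr) + abs(offs$dc) <= radius, ]
  dil <- function(px) {
    keys <- character(0)
    for (i in seq_len(nrow(offs))) {
      keys <- c(keys, paste(px[, 1] + offs$dr[i], px[, 2] + offs$dc[i]))
    }
    unique(keys)
  }
  length(intersect(dil(a), dil(b))) > 0
}

# exhaustive Otsu: try every threshold, maximize between-class variance
oracleOtsu <- function(values) {
  best <- -Inf; bestT <- NA_integer_
  for (t in 1:255) {
    lo <- values[values < t]; hi <- values[values >= t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo); w1 <- length(hi)
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best + 1e-9) { best <- s; bestT <- t }
  }
  bestT
}

# random connected graph: random spanning tree plus extra random edges
randomConnectedGraph <- function(n, extra = n) {
  perm <- sample.int(n)
  edges <- cbind(perm[-1], perm[vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))])
  if (extra > 0) {
    more <- cbind(sample.int(n, extra, replace = TRUE),
                  sample.int(n, extra, replace = TRUE))
    more <- more[more[, 1] != more[, 2], , drop = FALSE]
    edges <- rbind(edges, more)
  }
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  unique(edges)
}

# wrap an edge list as a CellGraph with minimal node table
edgeListGraph <- function(edges, n) {
  cellGraph(data.frame(label = seq_len(n)), edges)
}

# small, quick synthetic core spec for tests
tinySpec <- function(seed, ...) {
  syntheticCoreSpec(imageHeight = 384, imageWidth = 384, coreRadius = 165,
                    nTumorClusters = 3, tumorNucleiPerCluster = 6,
                    nStromaNuclei = 24, nOverstainedBlobs = 0,
                    rngSeed = seed, ...)
}

# rasterize a centred ellipse mask on an n x n grid
shapeMask <- function(a, b, n = 48) {
  g <- expand.grid(r = 1:n, c = 1:n)
  inside <- ((g$r - n / 2) / a)^2 + ((g$c - n / 2) / b)^2 <= 1
  L <- matrix(0L, n, n)
  L[cbind(g$r[inside], g$c[inside])] <- 1L
  L
}
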