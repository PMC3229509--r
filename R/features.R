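#' Canonical feature names and categories
#'
#' The 22 subgraph features: 10 topological graph metrics (category T)
#' followed by 12 averaged morphological (M) and intensity (I) node features.
#' The fixed order also serves as the tie-break in F-score ranking.
#'
#' @return named character vector mapping feature name to category.
#' @export
featureCategories <- function() {
  c(n_nodes = "T", n_edges = "T", avg_degree = "T", diameter = "T",
    radius = "T", n_central_points = "T", avg_clustering_coeff = "T",
    n_end_nodes = "T", pct_end_nodes = "T", hop_plot_exponent = "T",
    avg_area = "M", avg_eccentricity = "M", avg_equivalent_diameter = "M",
    avg_extent = "M", avg_major_axis = "M", avg_minor_axis = "M",
    avg_max_intensity = "I", avg_min_intensity = "I", avg_mean_intensity = "I",
    avg_perimeter = "M", avg_std_intensity = "I", avg_median_intensity = "I")
}

# the 12 per-nucleus features, in NucleusSet column order
.nodeFeatureCols <- c("area", "eccentricity", "equivalent_diameter", "extent",
                      "major_axis", "minor_axis", "max_intensity",
                      "min_intensity", "mean_intensity", "perimeter",
                      "std_intensity", "median_intensity")

#' Node eccentricities of a connected graph
#'
#' The eccentricity of a node is its maximum unweighted shortest-path distance
#' to any other node.
#'
#' @param graph a connected [CellGraph-class].
#' @return named integer vector (names are node labels).
#' @export
graphEccentricities <- function(graph) {
  d <- .graphDistances(graph)
  setNames(as.integer(apply(d, 1, max)), rownames(d))
}

.graphDistances <- function(graph) {
  ig <- .asIgraph(graph)
  d <- igraph::distances(ig)
  if (any(is.infinite(d))) stop("graph is not connected")
  d
}

#' Diameter, radius and central-point count
#'
#' Diameter = maximum eccentricity; radius = minimum eccentricity; central
#' points are the nodes whose eccentricity equals the radius.
#'
#' @param graph a connected [CellGraph-class].
#' @return named numeric vector \code{c(diameter, radius, n_central)}.
#' @export
diameterRadiusCentral <- function(graph) {
  ecc <- graphEccentricities(graph)
  r <- min(ecc)
  c(diameter = max(ecc), radius = r, n_central = sum(ecc == r))
}

#' Average clustering coefficient
#'
#' Mean over nodes of \eqn{C_i = 2 E_i / (k_i (k_i - 1))}, where \eqn{k_i} is
#' the number of neighbours of node i and \eqn{E_i} the number of edges among
#' them; nodes with fewer than two neighbours contribute 0.
#'
#' @param graph a [CellGraph-class].
#' @return numeric(1) in \code{[0, 1]}.
#' @export
avgClusteringCoefficient <- function(graph) {
  if (nrow(graphNodes(graph)) == 0) return(0)
  ig <- .asIgraph(graph)
  ci <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
  mean(ci)
}

#' End-node count and percentage
#'
#' End nodes are the nodes with degree exactly one.
#'
#' @param graph a [CellGraph-class].
#' @return named numeric vector \code{c(n_end, pct_end)}.
#' @export
endNodeStats <- function(graph) {
  n <- nrow(graphNodes(graph))
  deg <- igraph::degree(.asIgraph(graph))
  ne <- sum(deg == 1)
  c(n_end = ne, pct_end = if (n > 0) 100 * ne / n else 0)
}

#' Hop-plot values of a connected graph
#'
#' \eqn{P(h)} is the number of unordered node pairs whose shortest-path
#' distance is at most \code{h} hops, for \code{h = 1, ..., diameter}.
#'
#' @param graph a connected [CellGraph-class].
#' @return integer vector of length \code{diameter}.
#' @export
hopPlotValues <- function(graph) {
  d <- .graphDistances(graph)
  diam <- max(d)
  dv <- d[upper.tri(d)]
  vapply(seq_len(diam), function(h) sum(dv <= h), numeric(1))
}

#' Hop-plot exponent
#'
#' Least-squares slope of \eqn{\log P(h)} against \eqn{\log h} over
#' \code{h = 1, ..., diameter}; a topological density summary. Graphs of
#' diameter < 2 give a degenerate one-point regression; the exponent is then
#' defined as 0 (with a warning).
#'
#' @param graph a connected [CellGraph-class].
#' @return numeric(1).
#' @export
hopPlotExponent <- function(graph) {
  p <- hopPlotValues(graph)
  if (length(p) < 2) {
    warning("hop-plot exponent degenerate for diameter < 2; returning 0")
    return(0)
  }
  h <- seq_along(p)
  unname(coef(stats::lm(log(p) ~ log(h)))[2])
}

#' The 22-feature vector of one subgraph
#'
#' Ten topological metrics of the subgraph plus the unweighted arithmetic
#' means of the twelve per-nucleus shape/intensity features over its member
#' nuclei (already computed in the [NucleusSet-class] statistics the graph was
#' built from).
#'
#' @param graph a connected [CellGraph-class] with >= 2 nodes.
#' @return named numeric vector of length 22 (names and order as
#'   [featureCategories()]).
#' @export
graphFeatureVector <- function(graph) {
  nodes <- graphNodes(graph)
  if (nrow(nodes) < 2) stop("feature vector requires a subgraph of >= 2 nodes")
  drc <- diameterRadiusCentral(graph)
  ens <- endNodeStats(graph)
  nE <- nrow(graphEdges(graph))
  hp <- if (drc[["diameter"]] >= 2) hopPlotExponent(graph) else 0
  tvec <- c(
    n_nodes = nrow(nodes), n_edges = nE,
    avg_degree = 2 * nE / nrow(nodes),
    diameter = unname(drc["diameter"]), radius = unname(drc["radius"]),
    n_central_points = unname(drc["n_central"]),
    avg_clustering_coeff = avgClusteringCoefficient(graph),
    n_end_nodes = unname(ens["n_end"]), pct_end_nodes = unname(ens["pct_end"]),
    hop_plot_exponent = hp
  )
  mvec <- colMeans(nodes[, .nodeFeatureCols, drop = FALSE])
  names(mvec) <- paste0("avg_", .nodeFeatureCols)
  out <- c(tvec, mvec)
  out[names(featureCategories())]
}

#' Feature matrix of a list of subgraphs
#'
#' @param subgraphs list of connected [CellGraph-class]s (>= 2 nodes each).
#' @return data.frame with \code{subgraph_id} and the 22 feature columns.
#' @export
featureMatrix <- function(subgraphs) {
  feats <- names(featureCategories())
  if (!length(subgraphs)) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(feats) + 1),
                                  c("subgraph_id", feats)))
    return(out)
  }
  rows <- t(vapply(subgraphs, graphFeatureVector, numeric(length(feats))))
  out <- data.frame(subgraph_id = seq_along(subgraphs), rows, row.names = NULL)
  names(out) <- c("subgraph_id", feats)
  out
}

#' The 12 per-nucleus feature columns
#'
#' Extracts the morphological and intensity node features used by the
#' per-nucleus SVM of single-cell classification.
#'
#' @param nuclei a [NucleusSet-class] or its statistics data.frame.
#' @return data.frame with \code{label} plus the 12 feature columns.
#' @export
nodeFeatureMatrix <- function(nuclei) {
  df <- if (is(nuclei, "NucleusSet")) CellGraphTMA::nuclei(nuclei) else nuclei
  df[, c("label", .nodeFeatureCols), drop = FALSE]
}
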