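#' Do two nuclei touch after diamond dilation?
#'
#' Two nuclei are linked candidates when their pixel sets, each dilated with a
#' diamond structuring element of radius \code{radius}, intersect. For a
#' diamond (city-block ball) this is equivalent to the minimum L1 distance
#' between any pixel of one and any pixel of the other being at most
#' \code{2 * radius}; the implementation uses that characterization with a
#' bounding-box early exit.
#'
#' @param a,b two-column matrices of pixel coordinates (row, col).
#' @param radius diamond radius (>= 1); default 2, so nuclei within L1
#'   distance 4 touch.
#' @return logical(1).
#' @export
nucleiTouch <- function(a, b, radius = 2) {
  stopifnot(radius >= 1)
  lim <- 2 * radius
  # bbox gap lower-bounds the pixel L1 distance
  rgap <- max(0, max(min(b[, 1]) - max(a[, 1]), min(a[, 1]) - max(b[, 1])))
  cgap <- max(0, max(min(b[, 2]) - max(a[, 2]), min(a[, 2]) - max(b[, 2])))
  if (rgap + cgap > lim) return(FALSE)
  dr <- abs(outer(a[, 1], b[, 1], "-"))
  dc <- abs(outer(a[, 2], b[, 2], "-"))
  min(dr + dc) <= lim
}

#' Are two nuclei intensity-compatible?
#'
#' Tumor nuclei are typically darker than the connective-tissue nuclei that
#' surround them; linking is therefore vetoed when the arithmetic mean
#' intensities (over each nucleus's own pixel set) differ by
#' \code{threshold} or more (strictly-less-than rule).
#'
#' @param meanA,meanB mean intensities, or single rows of a
#'   [NucleusSet-class] statistics table.
#' @param threshold 8-bit intensity difference; default 30.
#' @return logical(1): \code{TRUE} iff \code{|meanA - meanB| < threshold}.
#' @export
intensityCompatible <- function(meanA, meanB, threshold = 30) {
  if (is.data.frame(meanA)) meanA <- meanA$mean_intensity
  if (is.data.frame(meanB)) meanB <- meanB$mean_intensity
  abs(meanA - meanB) < threshold
}

#' Build the cell graph of a segmented core
#'
#' Links every pair of nuclei that touch after diamond dilation
#' ([nucleiTouch()]) and whose mean intensities are compatible
#' ([intensityCompatible()]). Candidate pairs are restricted by bounding-box
#' proximity; the result is identical to the all-pairs definition.
#'
#' @param nucleusSet a [NucleusSet-class].
#' @param radius diamond structuring-element radius; default 2.
#' @param threshold intensity-difference veto threshold; default 30.
#' @return A [CellGraph-class] over all nuclei of the set.
#' @export
buildCellGraph <- function(nucleusSet, radius = 2, threshold = 30) {
  nuc <- nuclei(nucleusSet)
  lab <- labelImage(nucleusSet)
  n <- nrow(nuc)
  edges <- matrix(integer(0), 0, 2)
  if (n >= 2) {
    lim <- 2 * radius
    # candidate pairs: expanded bounding boxes within L1 reach
    cand <- list()
    ord <- order(nuc$bbox_min_row)
    for (ii in seq_len(n - 1)) {
      i <- ord[ii]
      for (jj in (ii + 1):n) {
        j <- ord[jj]
        if (nuc$bbox_min_row[j] - nuc$bbox_max_row[i] > lim) break
        rgap <- max(0, nuc$bbox_min_row[j] - nuc$bbox_max_row[i],
                       nuc$bbox_min_row[i] - nuc$bbox_max_row[j])
        cgap <- max(0, nuc$bbox_min_col[j] - nuc$bbox_max_col[i],
                       nuc$bbox_min_col[i] - nuc$bbox_max_col[j])
        if (rgap + cgap <= lim) cand[[length(cand) + 1L]] <- c(i, j)
      }
    }
    if (length(cand)) {
      bounds <- vector("list", n)   # lazily computed boundary pixel sets
      getB <- function(i) {
        if (is.null(bounds[[i]])) {
          id <- nuc$label[i]
          bounds[[i]] <<- .boundaryPixels(.labelPixels(lab, id), lab, id)
        }
        bounds[[i]]
      }
      keep <- vapply(cand, function(p) {
        i <- p[1]; j <- p[2]
        intensityCompatible(nuc$mean_intensity[i], nuc$mean_intensity[j], threshold) &&
          nucleiTouch(getB(i), getB(j), radius)
      }, logical(1))
      cand <- cand[keep]
      if (length(cand)) {
        edges <- do.call(rbind, lapply(cand, function(p) nuc$label[p]))
      }
    }
  }
  cellGraph(nuc, edges)
}

#' Decompose a cell graph into connected subgraphs
#'
#' Maximal connected components with at least two nodes are returned as
#' subgraphs (the units the tissue classifier operates on); degree-zero nuclei
#' are returned separately and handled by single-cell classification.
#'
#' @param graph a [CellGraph-class].
#' @return list with \code{subgraphs} (list of connected [CellGraph-class]s)
#'   and \code{isolated} (data.frame of degree-0 nuclei).
#' @export
connectedSubgraphs <- function(graph) {
  nodes <- graphNodes(graph)
  edges <- graphEdges(graph)
  if (!nrow(edges)) {
    return(list(subgraphs = list(), isolated = nodes))
  }
  linked <- sort(unique(as.integer(edges)))
  iso <- nodes[!nodes$label %in% linked, , drop = FALSE]
  ig <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2), directed = FALSE)
  comp <- igraph::components(ig)
  memb <- split(as.integer(igraph::V(ig)$name), comp$membership)
  subs <- lapply(memb, function(labs) {
    sel <- edges[, 1] %in% labs & edges[, 2] %in% labs
    cellGraph(nodes[nodes$label %in% labs, , drop = FALSE],
              edges[sel, , drop = FALSE])
  })
  # deterministic order: by smallest member label
  ord <- order(vapply(subs, function(g) min(graphNodes(g)$label), numeric(1)))
  list(subgraphs = unname(subs[ord]), isolated = iso)
}

# internal igraph view of a CellGraph (vertex name = nucleus label)
.asIgraph <- function(graph) {
  nodes <- graphNodes(graph)
  edges <- graphEdges(graph)
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$label))
  )
}
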