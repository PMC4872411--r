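# Census of the eight connected undirected 3-4-node motif classes.

.motifNames <- c("path3", "triangle", "path4", "star4", "cycle4", "paw",
                 "diamond", "K4")
.cyclicClasses <- c("triangle", "cycle4", "paw", "diamond", "K4")

#' The fixed catalogue of connected undirected 3-4-node motifs
#'
#' All isomorphism classes of connected undirected graphs on 3 nodes
#' (2 classes) and 4 nodes (6 classes), in a fixed order so output columns
#' are stable: path3, triangle, path4, star4, cycle4, paw, diamond, K4.
#' A class is cyclic iff it contains a cycle, equivalently iff it has at
#' least as many edges as nodes; cyclic = {triangle, cycle4, paw, diamond,
#' K4}, acyclic (trees) = {path3, path4, star4}.
#'
#' @return data.frame with columns \code{class}, \code{nodes},
#'   \code{edges}, \code{cyclic}, and a list-column \code{adjacency} of
#'   canonical adjacency matrices.
#' @export
motifCatalogue <- function() {
  defs <- list(
    path3    = c(1,2, 2,3),
    triangle = c(1,2, 2,3, 1,3),
    path4    = c(1,2, 2,3, 3,4),
    star4    = c(1,2, 1,3, 1,4),
    cycle4   = c(1,2, 2,3, 3,4, 1,4),
    paw      = c(1,2, 2,3, 1,3, 3,4),
    diamond  = c(1,2, 2,3, 3,4, 1,4, 1,3),
    K4       = c(1,2, 1,3, 1,4, 2,3, 2,4, 3,4))
  adj <- lapply(names(defs), function(nm) {
    n <- if (nm %in% c("path3", "triangle")) 3L else 4L
    adjacencyMatrix(.bnFromEdges(n, defs[[nm]]))
  })
  out <- data.frame(class = .motifNames,
                    nodes = c(3L, 3L, rep(4L, 6L)),
                    edges = vapply(adj, function(a) sum(a) / 2, 0),
                    cyclic = .motifNames %in% .cyclicClasses,
                    stringsAsFactors = FALSE)
  out$adjacency <- adj
  out
}

#' Motif census of a binary network
#'
#' Counts connected *induced* subgraphs on 3 and 4 nodes, classified by
#' isomorphism to the fixed catalogue. Induced counting is what makes the
#' eight classes a partition of the connected vertex sets (it
#' distinguishes e.g. a diamond from a 4-cycle). Enumeration uses
#' ESU-style connected-subgraph expansion, visiting each connected vertex
#' set exactly once, so the cost scales with the number of connected
#' subgraphs rather than with choose(N, 4). Frequencies are raw counts;
#' conditions compared at matched density have comparable counts by
#' construction.
#'
#' @param g a \linkS4class{BinaryNetwork}.
#' @return A \linkS4class{MotifCensus}.
#' @export
motifCensus <- function(g) {
  stopifnot(is(g, "BinaryNetwork"))
  counts <- motif_census_cpp(g@adjacency)
  names(counts) <- .motifNames
  new("MotifCensus", counts = counts, density = g@density)
}

#' Cyclic and acyclic motif totals
#'
#' Sums a census over the fixed cyclic/acyclic partition.
#'
#' @param census a \linkS4class{MotifCensus}.
#' @return named numeric vector \code{c(cyclic = ..., acyclic = ...)}.
#' @export
cyclicAcyclicTotals <- function(census) {
  stopifnot(is(census, "MotifCensus"))
  cyc <- names(census@counts) %in% .cyclicClasses
  c(cyclic = sum(census@counts[cyc]), acyclic = sum(census@counts[!cyc]))
}
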