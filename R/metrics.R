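# The five binary graph metrics: mean clustering coefficient (C),
# characteristic path length (L), global efficiency (Eglob), local
# efficiency (Eloc), and small-worldness (sigma) against a null ensemble.

#' Mean clustering coefficient (Watts-Strogatz)
#'
#' Mean over nodes of 2 t_i / (k_i (k_i - 1)), where t_i is the number of
#' triangles through node i; nodes with degree < 2 contribute 0.
#'
#' @param g a \linkS4class{BinaryNetwork}.
#' @return scalar in [0, 1].
#' @export
clusteringCoefficient <- function(g) {
  stopifnot(is(g, "BinaryNetwork"))
  a <- g@adjacency
  n <- nrow(a)
  if (n == 0) return(0)
  k <- rowSums(a)
  # (A^2 * A) summed over rows = 2 * triangles per node
  tri2 <- rowSums((a %*% a) * a)
  ci <- ifelse(k >= 2, tri2 / (k * (k - 1)), 0)
  mean(ci)
}

#' All-pairs shortest hop distances (BFS)
#'
#' @param g a \linkS4class{BinaryNetwork}.
#' @return N x N matrix of hop counts; unreachable pairs are \code{Inf},
#'   the diagonal is 0.
#' @export
shortestPathLengths <- function(g) {
  stopifnot(is(g, "BinaryNetwork"))
  d <- bfs_distances_cpp(g@adjacency)
  d[is.na(d)] <- Inf
  storage.mode(d) <- "double"
  dimnames(d) <- list(g@regionLabels, g@regionLabels)
  d
}

#' Characteristic path length over reachable pairs
#'
#' Mean of the finite off-diagonal distances over reachable ordered pairs.
#' Unreachable pairs are excluded from the mean and counted, because sparse
#' thresholded networks fragment and L is very sensitive to that; the count
#' is reported so fragmentation is never silent.
#'
#' @param g a \linkS4class{BinaryNetwork}.
#' @return list with \code{L} (scalar) and \code{nUnreachablePairs}
#'   (ordered-pair count).
#' @export
characteristicPathLength <- function(g) {
  stopifnot(is(g, "BinaryNetwork"))
  .cplAdj(g@adjacency)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of 1/d(i,j), with 1/Inf = 0 for
#' unreachable pairs, which makes the measure robust to fragmentation.
#'
#' @param g a \linkS4class{BinaryNetwork}.
#' @return scalar in [0, 1]; 0 for an edgeless graph.
#' @export
globalEfficiency <- function(g) {
  stopifnot(is(g, "BinaryNetwork"))
  if (nrow(g@adjacency) < 2) return(0)
  .globalEfficiencyAdj(g@adjacency)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by the
#' node's neighbours (the node itself excluded); nodes with fewer than two
#' neighbours contribute 0.
#'
#' @param g a \linkS4class{BinaryNetwork}.
#' @return scalar in [0, 1].
#' @export
localEfficiency <- function(g) {
  stopifnot(is(g, "BinaryNetwork"))
  local_efficiency_cpp(g@adjacency)
}

#' Small-worldness sigma
#'
#' \eqn{\sigma = (C/\bar C_{rand}) / (L/\bar L_{rand})}, where the
#' reference means are taken over a seeded null ensemble (degree-preserving
#' rewiring by default). L on the nulls uses the same reachable-pairs
#' convention as on the observed graph.
#'
#' @param g a \linkS4class{BinaryNetwork}.
#' @param nulls a \linkS4class{NullEnsembleSpec}.
#' @return scalar sigma (> 0).
#' @export
smallWorldness <- function(g, nulls = nullEnsembleSpec()) {
  obs <- list(C = clusteringCoefficient(g), L = characteristicPathLength(g)$L)
  ref <- nullEnsembleStats(g, nulls)
  if (ref$Cbar == 0) stop("degenerate null ensemble: mean clustering is 0")
  (obs$C / ref$Cbar) / (obs$L / ref$Lbar)
}

#' Bundle the five metrics for one network
#'
#' @param g a \linkS4class{BinaryNetwork}.
#' @param nulls a \linkS4class{NullEnsembleSpec} (needed when sigma is
#'   requested).
#' @param metrics which metrics to compute.
#' @return Named list with the requested metrics plus
#'   \code{nUnreachablePairs} and \code{density}. Metrics that are
#'   undefined on the given graph (e.g. L on an edgeless graph) come back
#'   as \code{NA} with the reason in the \code{notes} element, never
#'   silently dropped.
#' @export
metricVector <- function(g, nulls = nullEnsembleSpec(),
                         metrics = c("C", "L", "Eglob", "Eloc", "sigma")) {
  out <- list(density = g@density)
  notes <- character()
  a <- g@adjacency
  ps <- path_stats_cpp(a)
  needCL <- any(c("C", "L", "sigma") %in% metrics)
  cc <- if (needCL) .clusteringAdj(a) else NULL
  cpl <- if (!needCL) NULL
         else if (is.na(ps[1])) simpleError("no reachable pairs: graph is edgeless")
         else list(L = ps[1], nUnreachablePairs = as.integer(ps[2]))
  if ("C" %in% metrics) out$C <- cc
  if (any(c("L", "sigma") %in% metrics)) {
    if (inherits(cpl, "error")) {
      out$L <- NA_real_
      out$nUnreachablePairs <- NA_integer_
      notes["L"] <- conditionMessage(cpl)
    } else {
      out$L <- cpl$L
      out$nUnreachablePairs <- cpl$nUnreachablePairs
    }
  }
  if ("Eglob" %in% metrics) out$Eglob <- ps[3]
  if ("Eloc" %in% metrics) out$Eloc <- local_efficiency_cpp(a)
  if ("sigma" %in% metrics) {
    if (inherits(cpl, "error")) {
      out$sigma <- NA_real_
      notes["sigma"] <- "L undefined, sigma unavailable"
    } else {
      ref <- nullEnsembleStats(g, nulls)
      if (ref$Cbar == 0) {
        out$sigma <- NA_real_
        notes["sigma"] <- "degenerate null ensemble: mean clustering is 0"
      } else {
        out$sigma <- (cc / ref$Cbar) / (cpl$L / ref$Lbar)
      }
    }
  }
  out$notes <- notes
  out
}
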