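# Random reference networks for sigma normalization.

# Fast internal paths on raw adjacency matrices (no S4 construction per
# null; the exported functions validate once and delegate here).
.clusteringAdj <- function(a) {
  k <- rowSums(a)
  tri2 <- rowSums((a %*% a) * a)
  mean(ifelse(k >= 2, tri2 / (k * (k - 1)), 0))
}

.cplAdj <- function(a) {
  ps <- path_stats_cpp(a)
  if (is.na(ps[1])) stop("no reachable pairs: graph is edgeless")
  list(L = ps[1], nUnreachablePairs = as.integer(ps[2]))
}

.globalEfficiencyAdj <- function(a) path_stats_cpp(a)[3]

# Ensemble means of C and L over rewired (or ER-matched) nulls of the
# adjacency `a`; runs inside an already-seeded stream.
.nullStatsRaw <- function(a, spec) {
  n <- nrow(a)
  e <- which(upper.tri(a) & a == 1L, arr.ind = TRUE)
  m <- nrow(e)
  cs <- numeric(spec@nNulls)
  ls <- numeric(spec@nNulls)
  acc <- numeric(spec@nNulls)
  for (i in seq_len(spec@nNulls)) {
    if (spec@method == "rewire_degree_preserving") {
      res <- rewire_cpp(e - 1L, n, as.integer(spec@swapsPerEdge) * m)
      an <- matrix(0L, n, n)
      idx <- res$edges + 1L
      an[idx] <- 1L
      an[idx[, 2:1, drop = FALSE]] <- 1L
      acc[i] <- res$accepted / res$attempted
    } else {
      ut <- which(upper.tri(a))
      an <- matrix(0L, n, n)
      an[sample(ut, m)] <- 1L
      an <- an + t(an)
      acc[i] <- NA_real_
    }
    cs[i] <- .clusteringAdj(an)
    ls[i] <- .cplAdj(an)$L
  }
  list(Cbar = mean(cs), Lbar = mean(ls), C = cs, L = ls,
       acceptanceRate = mean(acc))
}

#' Degree-preserving rewiring (double-edge swaps)
#'
#' Attempts \code{swapsPerEdge * |E|} double-edge swaps
#' (a-b, c-d -> a-d, c-b), accepting a swap only when it creates no
#' self-loop or multi-edge, so the degree sequence is conserved exactly.
#' The attempt budget counts attempts, not acceptances; the realized
#' acceptance rate is attached as attribute \code{acceptanceRate}. If no
#' proposal is accepted within the budget (e.g. a complete graph admits no
#' legal swap) the input is returned unchanged with a warning.
#'
#' @param g a \linkS4class{BinaryNetwork} with at least 2 edges.
#' @param spec a \linkS4class{NullEnsembleSpec}; only \code{swapsPerEdge}
#'   is used here.
#' @param seed optional seed; by default the caller's RNG stream is used
#'   (the ensemble functions seed once for the whole ensemble).
#' @return Rewired \linkS4class{BinaryNetwork}.
#' @export
rewireDegreePreserving <- function(g, spec = nullEnsembleSpec(), seed = NULL) {
  stopifnot(is(g, "BinaryNetwork"))
  e <- .edgeIndices(g)
  m <- nrow(e)
  if (m < 2) stop("need at least 2 edges to rewire")
  run <- function() rewire_cpp(e - 1L, nrow(g@adjacency),
                               as.integer(spec@swapsPerEdge) * m)
  res <- if (is.null(seed)) run() else .withSeed(seed, run())
  if (res$accepted == 0)
    warning("no legal swap found within the attempt budget; returning the graph unchanged")
  n <- nrow(g@adjacency)
  a <- matrix(0L, n, n)
  idx <- res$edges + 1L
  a[idx] <- 1L
  a[idx[, 2:1, drop = FALSE]] <- 1L
  out <- binaryNetwork(a, regionLabels = g@regionLabels, density = g@density)
  attr(out, "acceptanceRate") <- res$accepted / res$attempted
  out
}

#' Erdos-Renyi null with matched node and edge counts
#'
#' Draws G(N, M) uniformly: M node pairs sampled without replacement.
#'
#' @inheritParams rewireDegreePreserving
#' @export
erdosRenyiMatched <- function(g, spec = nullEnsembleSpec(), seed = NULL) {
  stopifnot(is(g, "BinaryNetwork"))
  n <- nrow(g@adjacency)
  m <- edgeCount(g)
  ut <- which(upper.tri(g@adjacency))
  pick <- function() sample(ut, m)
  keep <- if (is.null(seed)) pick() else .withSeed(seed, pick())
  a <- matrix(0L, n, n)
  a[keep] <- 1L
  a <- a + t(a)
  binaryNetwork(a, regionLabels = g@regionLabels, density = g@density)
}

#' Null-ensemble reference statistics for sigma
#'
#' Generates \code{nNulls} null networks (method per the spec) under a
#' single seeded RNG stream and returns the ensemble means of clustering
#' and characteristic path length. Connectedness is deliberately not
#' enforced (rejection for connectedness would bias the ensemble); L uses
#' the reachable-pairs convention. Reproducible bit-exactly given
#' (graph, spec).
#'
#' @param g a \linkS4class{BinaryNetwork}.
#' @param spec a \linkS4class{NullEnsembleSpec}.
#' @return list with \code{Cbar}, \code{Lbar}, and the per-null vectors
#'   \code{C}, \code{L}, plus the mean swap \code{acceptanceRate} for the
#'   rewiring method.
#' @export
nullEnsembleStats <- function(g, spec = nullEnsembleSpec()) {
  stopifnot(is(g, "BinaryNetwork"), is(spec, "NullEnsembleSpec"))
  validObject(spec)
  .withSeed(spec@seed, .nullStatsRaw(g@adjacency, spec))
}
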