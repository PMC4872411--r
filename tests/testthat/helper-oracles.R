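# Shared helpers: graph builders, random graphs, and independent
# brute-force oracles (igraph for distances/clustering, exhaustive
# vertex-subset enumeration for the motif census).

bnFromEdgeVec <- function(n, edges) {
  a <- matrix(0L, n, n)
  if (length(edges)) {
    e <- matrix(as.integer(edges), ncol = 2, byrow = TRUE)
    a[e] <- 1L
    a[e[, 2:1, drop = FALSE]] <- 1L
  }
  binaryNetwork(a)
}

bnFromAdj <- function(a) binaryNetwork(a)

randomGraph <- function(n, p) {
  a <- matrix(0L, n, n)
  ut <- which(upper.tri(a))
  a[ut] <- as.integer(runif(length(ut)) < p)
  a + t(a)
}

# all labeled graphs on n nodes (n small), as adjacency matrices
allGraphs <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)))
  m <- length(ut)
  lapply(0:(2^m - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    a <- matrix(0L, n, n)
    a[ut] <- bits
    a + t(a)
  })
}

toIgraph <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected", diag = FALSE)
}

# Independent metric oracle built on igraph distances / transitivity.
metricOracle <- function(a) {
  g <- toIgraph(a)
  n <- nrow(a)
  ctri <- igraph::transitivity(g, type = "local", isolates = "zero")
  # igraph's "local" leaves NaN for degree-1 nodes in some versions
  ctri[is.na(ctri)] <- 0
  d <- igraph::distances(g)
  off <- d[row(d) != col(d)]
  fin <- is.finite(off)
  L <- if (any(fin)) mean(off[fin]) else NA_real_
  eglob <- if (n > 1) mean(ifelse(fin, 1 / off, 0)) else 0
  eloc <- 0
  if (n > 0) {
    vals <- vapply(seq_len(n), function(i) {
      nb <- which(a[i, ] == 1L)
      if (length(nb) < 2) return(0)
      sub <- a[nb, nb, drop = FALSE]
      ds <- igraph::distances(toIgraph(sub))
      offs <- ds[row(ds) != col(ds)]
      mean(ifelse(is.finite(offs), 1 / offs, 0))
    }, 0)
    eloc <- mean(vals)
  }
  list(C = mean(ctri), L = L, nUnreachable = sum(!fin), Eglob = eglob,
       Eloc = eloc)
}

# Brute-force census oracle: test every 3- and 4-vertex subset for
# connectedness and classify by edge count + maximum degree.
censusOracle <- function(a) {
  n <- nrow(a)
  counts <- setNames(numeric(8), c("path3", "triangle", "path4", "star4",
                                   "cycle4", "paw", "diamond", "K4"))
  if (n >= 3) {
    for (s in asplit(combn(n, 3), 2)) {
      sub <- a[s, s]
      ec <- sum(sub) / 2
      if (ec == 2) counts["path3"] <- counts["path3"] + 1
      if (ec == 3) counts["triangle"] <- counts["triangle"] + 1
    }
  }
  if (n >= 4) {
    for (s in asplit(combn(n, 4), 2)) {
      sub <- a[s, s]
      ec <- sum(sub) / 2
      deg <- rowSums(sub)
      if (ec == 3 && min(deg) >= 1)
        counts[if (max(deg) == 3) "star4" else "path4"] <-
          counts[if (max(deg) == 3) "star4" else "path4"] + 1
      if (ec == 4)
        counts[if (max(deg) == 3) "paw" else "cycle4"] <-
          counts[if (max(deg) == 3) "paw" else "cycle4"] + 1
      if (ec == 5) counts["diamond"] <- counts["diamond"] + 1
      if (ec == 6) counts["K4"] <- counts["K4"] + 1
    }
  }
  counts
}

expect_metrics_match_oracle <- function(a, tol = 1e-12) {
  g <- bnFromAdj(a)
  o <- metricOracle(a)
  expect_equal(clusteringCoefficient(g), o$C, tolerance = tol)
  expect_equal(globalEfficiency(g), o$Eglob, tolerance = tol)
  expect_equal(localEfficiency(g), o$Eloc, tolerance = tol)
  if (!is.na(o$L)) {
    cpl <- characteristicPathLength(g)
    expect_equal(cpl$L, o$L, tolerance = tol)
    expect_equal(cpl$nUnreachablePairs, o$nUnreachable)
  } else {
    expect_error(characteristicPathLength(g), "no reachable pairs")
  }
}
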