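# Constructors, accessors and show methods.

#' Construct a RoiTimeSeries
#'
#' @param values T x N numeric matrix (rows = time points).
#' @param regionLabels region names; defaults to \code{colnames(values)} or
#'   \code{R1..RN}.
#' @param samplingInterval sampling interval in seconds.
#' @param subjectId,condition,group session metadata.
#' @return A \linkS4class{RoiTimeSeries}.
#' @examples
#' ts <- roiTimeSeries(matrix(rnorm(40), 10, 4), samplingInterval = 2)
#' dim(tsMatrix(ts))
#' @export
roiTimeSeries <- function(values, regionLabels = NULL, samplingInterval = 1,
                          subjectId = NA_character_, condition = NA_character_,
                          group = NA_character_) {
  values <- as.matrix(values)
  if (is.null(regionLabels))
    regionLabels <- colnames(values)
  if (is.null(regionLabels))
    regionLabels <- paste0("R", seq_len(ncol(values)))
  colnames(values) <- regionLabels
  new("RoiTimeSeries", values = values, regionLabels = as.character(regionLabels),
      samplingInterval = samplingInterval,
      subjectId = as.character(subjectId), condition = as.character(condition),
      group = as.character(group))
}

#' Construct a ConnectivityMatrix
#'
#' @param z symmetric Fisher-z matrix with zero diagonal.
#' @param regionLabels node labels (defaults to rownames).
#' @param subjectId,condition,group provenance metadata.
#' @export
connectivityMatrix <- function(z, regionLabels = NULL,
                               subjectId = NA_character_,
                               condition = NA_character_,
                               group = NA_character_) {
  z <- as.matrix(z)
  if (is.null(regionLabels)) regionLabels <- rownames(z)
  if (is.null(regionLabels)) regionLabels <- paste0("R", seq_len(nrow(z)))
  dimnames(z) <- list(regionLabels, regionLabels)
  new("ConnectivityMatrix", z = z, regionLabels = as.character(regionLabels),
      subjectId = as.character(subjectId), condition = as.character(condition),
      group = as.character(group))
}

#' Construct a BinaryNetwork
#'
#' @param adjacency symmetric 0/1 matrix, zero diagonal.
#' @param regionLabels node labels.
#' @param density stated density; computed from the edge count if missing.
#' @export
binaryNetwork <- function(adjacency, regionLabels = NULL, density = NULL) {
  a <- as.matrix(adjacency)
  storage.mode(a) <- "integer"
  n <- nrow(a)
  if (is.null(regionLabels)) regionLabels <- rownames(a)
  if (is.null(regionLabels)) regionLabels <- paste0("R", seq_len(n))
  dimnames(a) <- list(regionLabels, regionLabels)
  if (is.null(density))
    density <- if (n > 1) sum(a[upper.tri(a)]) / (n * (n - 1) / 2) else 0
  new("BinaryNetwork", adjacency = a, density = as.numeric(density),
      regionLabels = as.character(regionLabels))
}

# small helper used throughout: edge list from a BinaryNetwork (0-based for C++)
.edgeIndices <- function(g) {
  a <- g@adjacency
  which(upper.tri(a) & a == 1L, arr.ind = TRUE)
}

#' @rdname roiTimeSeries
#' @param object,x an object of the matching class.
#' @export
setGeneric("tsMatrix", function(x) standardGeneric("tsMatrix"))
#' @rdname roiTimeSeries
#' @export
setMethod("tsMatrix", "RoiTimeSeries", function(x) x@values)

#' Accessors shared across the pipeline's containers
#'
#' \code{regionLabels} returns node/region labels; \code{samplingInterval}
#' the sampling interval in seconds; \code{zMatrix} the Fisher-z matrix;
#' \code{adjacencyMatrix} the 0/1 adjacency; \code{networkDensity} the
#' stated density; \code{edgeCount} the number of undirected edges;
#' \code{motifCounts} the named motif count vector; \code{nbsComponents}
#' the list of supra-threshold components.
#'
#' @param x an object of the matching class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setMethod("regionLabels", "RoiTimeSeries", function(x) x@regionLabels)
#' @rdname accessors
#' @export
setMethod("regionLabels", "ConnectivityMatrix", function(x) x@regionLabels)
#' @rdname accessors
#' @export
setMethod("regionLabels", "BinaryNetwork", function(x) x@regionLabels)

#' @rdname accessors
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))
#' @rdname accessors
#' @export
setMethod("samplingInterval", "RoiTimeSeries", function(x) x@samplingInterval)

#' @rdname accessors
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))
#' @rdname accessors
#' @export
setMethod("zMatrix", "ConnectivityMatrix", function(x) x@z)

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))
#' @rdname accessors
#' @export
setMethod("adjacencyMatrix", "BinaryNetwork", function(x) x@adjacency)

#' @rdname accessors
#' @export
setGeneric("networkDensity", function(x) standardGeneric("networkDensity"))
#' @rdname accessors
#' @export
setMethod("networkDensity", "BinaryNetwork", function(x) x@density)
#' @rdname accessors
#' @export
setMethod("networkDensity", "MotifCensus", function(x) x@density)

#' @rdname accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
#' @rdname accessors
#' @export
setMethod("edgeCount", "BinaryNetwork", function(x) {
  a <- x@adjacency
  as.integer(sum(a[upper.tri(a)]))
})

#' @rdname accessors
#' @export
setGeneric("motifCounts", function(x) standardGeneric("motifCounts"))
#' @rdname accessors
#' @export
setMethod("motifCounts", "MotifCensus", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("nbsComponents", function(x) standardGeneric("nbsComponents"))
#' @rdname accessors
#' @export
setMethod("nbsComponents", "NBSResult", function(x) x@components)

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries: %d time points x %d regions (TR = %gs)\n",
              nrow(object@values), ncol(object@values), object@samplingInterval))
  cat(sprintf("  subject: %s  condition: %s  group: %s\n",
              object@subjectId, object@condition, object@group))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix: %d x %d Fisher-z (subject %s, condition %s)\n",
              nrow(object@z), ncol(object@z), object@subjectId, object@condition))
})

setMethod("show", "BinaryNetwork", function(object) {
  cat(sprintf("BinaryNetwork: %d nodes, %d edges (density %.4f)\n",
              nrow(object@adjacency), edgeCount(object), object@density))
})

setMethod("show", "MotifCensus", function(object) {
  cat("MotifCensus (connected undirected 3-4-node induced subgraphs)\n")
  print(object@counts)
})

setMethod("show", "NBSResult", function(object) {
  cat(sprintf("NBSResult: %d supra-threshold component(s)\n",
              length(object@components)))
  for (comp in object@components)
    cat(sprintf("  size %d edges / %d nodes, p_fwer = %.4g\n",
                comp$size, length(comp$nodes), comp$pFwer))
})

# ---- parameter constructors ---------------------------------------------

#' Latent network specification for the synthetic-data generator
#'
#' Defaults describe the study-emulation conditions used throughout the
#' package's benchmarks: strongly coupled modules (dense within-module
#' latent edges) joined by sparser, weaker between-module edges, so the
#' thresholded networks sit in a small-world regime where between-module
#' links act as shortcuts.
#'
#' @param nNodes number of regions.
#' @param nModules number of near-equal modules.
#' @param pWithin,pBetween latent edge probabilities (within/between
#'   modules); 0 <= pBetween <= pWithin <= 1.
#' @param coupling scalar c in Sigma = I + c W / rho(W0); must keep the
#'   result positive definite (checked).
#' @param weightWithin,weightBetween baseline latent edge weights, to which
#'   condition effects add their deltas.
#' @param nodeStrengthSd sd of the lognormal node-strength factors; edge
#'   weights are multiplied by s_i s_j, so positive values give the latent
#'   network hubs (heterogeneous degree) as empirical functional brain
#'   networks have. Default 0 (homogeneous), which gives the clearest
#'   planted-effect recovery at desk scale.
#' @param seed seed for sampling the latent edge pattern.
#' @return A \linkS4class{LatentNetworkSpec}.
#' @export
latentNetworkSpec <- function(nNodes, nModules = max(1L, round(nNodes / 12)),
                              pWithin = 0.9, pBetween = 0.05,
                              coupling = 0.85, weightWithin = 1,
                              weightBetween = 0.2, nodeStrengthSd = 0,
                              seed = 1L) {
  new("LatentNetworkSpec", nNodes = as.integer(nNodes),
      nModules = as.integer(nModules), pWithin = pWithin,
      pBetween = pBetween, coupling = coupling,
      weightWithin = weightWithin, weightBetween = weightBetween,
      nodeStrengthSd = nodeStrengthSd, seed = as.integer(seed))
}

#' Condition effect on the latent coupling
#'
#' @param deltaWithin,deltaBetween signed shifts of the within-/between-
#'   module latent weights.
#' @param label condition label, e.g. "placebo" or "drug".
#' @export
conditionEffect <- function(deltaWithin = 0, deltaBetween = 0,
                            label = "placebo") {
  new("ConditionEffect", deltaWithin = deltaWithin,
      deltaBetween = deltaBetween, label = label)
}

#' Study design specification
#'
#' @param design "paired" or "two_group".
#' @param nSubjects subjects (paired) or per-group count (two_group).
#' @param nTimepoints time points per session.
#' @param samplingInterval seconds.
#' @param arCoefficient AR(1) coefficient, default 0.3.
#' @param subjectEffectSd sd of the lognormal subject coupling jitter.
#' @param seed master seed.
#' @export
studyDesignSpec <- function(design = c("paired", "two_group"), nSubjects = 20L,
                            nTimepoints = 300L, samplingInterval = 1.79,
                            arCoefficient = 0.3, subjectEffectSd = 0.1,
                            seed = 1L) {
  new("StudyDesignSpec", design = match.arg(design),
      nSubjects = as.integer(nSubjects), nTimepoints = as.integer(nTimepoints),
      samplingInterval = samplingInterval, arCoefficient = arCoefficient,
      subjectEffectSd = subjectEffectSd, seed = as.integer(seed))
}

#' Null ensemble specification for small-worldness
#'
#' @param nNulls ensemble size.
#' @param swapsPerEdge attempted double-edge swaps per edge.
#' @param method "rewire_degree_preserving" or "erdos_renyi_matched".
#' @param seed RNG seed.
#' @export
nullEnsembleSpec <- function(nNulls = 100L, swapsPerEdge = 10L,
                             method = c("rewire_degree_preserving",
                                        "erdos_renyi_matched"),
                             seed = 1L) {
  new("NullEnsembleSpec", nNulls = as.integer(nNulls),
      swapsPerEdge = as.integer(swapsPerEdge), method = match.arg(method),
      seed = as.integer(seed))
}

#' Density sweep configuration
#'
#' @param densities strictly increasing density grid; default
#'   \code{seq(0.05, 0.20, by = 0.01)} (16 levels).
#' @param nullSpec \linkS4class{NullEnsembleSpec} for sigma.
#' @param metrics metrics to compute; subset of C, L, Eglob, Eloc, sigma.
#' @param motifs run the motif census at each density.
#' @param rankAbsolute rank edges by absolute z rather than signed z.
#' @export
sweepConfig <- function(densities = seq(0.05, 0.20, by = 0.01),
                        nullSpec = nullEnsembleSpec(),
                        metrics = c("C", "L", "Eglob", "Eloc", "sigma"),
                        motifs = TRUE, rankAbsolute = FALSE) {
  new("SweepConfig", densities = densities, nullSpec = nullSpec,
      metrics = metrics, motifs = motifs, rankAbsolute = rankAbsolute)
}

#' NBS configuration
#'
#' @param primaryThresholdT primary t threshold on edges (required; no
#'   default is provided because reported components are conditional on
#'   this choice).
#' @param nPermutations permutation count (default 5000).
#' @param alpha FWER level.
#' @param tail "greater" (default), "less" or "two_sided".
#' @param design "paired" (sign flips) or "two_group" (label shuffles).
#' @param componentSize "extent" (edge count, default) or "intensity"
#'   (sum of supra-threshold exceedances).
#' @param seed permutation RNG seed.
#' @export
nbsConfig <- function(primaryThresholdT, nPermutations = 5000L, alpha = 0.05,
                      tail = c("greater", "less", "two_sided"),
                      design = c("paired", "two_group"),
                      componentSize = c("extent", "intensity"), seed = 1L) {
  if (missing(primaryThresholdT))
    stop("'primaryThresholdT' is required (no default)")
  new("NBSConfig", primaryThresholdT = primaryThresholdT,
      nPermutations = as.integer(nPermutations), alpha = alpha,
      tail = match.arg(tail), design = match.arg(design),
      componentSize = match.arg(componentSize), seed = as.integer(seed))
}
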