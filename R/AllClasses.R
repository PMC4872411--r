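# S4 containers for the pipeline's central objects, plus lightweight
# parameter classes whose validity methods encode the design invariants.

#' RoiTimeSeries: one subject-session's regional time series
#'
#' A T x N matrix of regional signals (rows = time points, columns =
#' labelled regions) plus the sampling interval and session metadata.
#'
#' @slot values numeric matrix, T x N, no missing values.
#' @slot regionLabels character of length N, unique, order-stable.
#' @slot samplingInterval sampling interval (repetition time) in seconds.
#' @slot subjectId,condition,group session metadata; free-form strings.
#' @export
setClass("RoiTimeSeries",
  representation(values = "matrix", regionLabels = "character",
                 samplingInterval = "numeric", subjectId = "character",
                 condition = "character", group = "character"),
  prototype(samplingInterval = 1, subjectId = NA_character_,
            condition = NA_character_, group = NA_character_))

setValidity("RoiTimeSeries", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (anyNA(v) || any(!is.finite(v))) return("'values' contains missing/non-finite entries")
  if (nrow(v) < 1L) return("at least one time point is required")
  n <- ncol(v)
  if (length(object@regionLabels) != n)
    return(sprintf("expected %d region labels, got %d", n, length(object@regionLabels)))
  if (anyDuplicated(object@regionLabels))
    return("region labels must be unique")
  if (length(object@samplingInterval) != 1L || !is.finite(object@samplingInterval) ||
      object@samplingInterval <= 0)
    return("'samplingInterval' must be a single positive number (seconds)")
  TRUE
})

#' ConnectivityMatrix: symmetric Fisher-z functional connectivity
#'
#' Pairwise Pearson correlations transformed to Fisher z (atanh), with an
#' exactly zero diagonal.
#'
#' @slot z numeric N x N matrix, symmetric, zero diagonal, finite.
#' @slot regionLabels character of length N.
#' @slot subjectId,condition,group provenance carried from the session.
#' @export
setClass("ConnectivityMatrix",
  representation(z = "matrix", regionLabels = "character",
                 subjectId = "character", condition = "character",
                 group = "character"),
  prototype(subjectId = NA_character_, condition = NA_character_,
            group = NA_character_))

setValidity("ConnectivityMatrix", function(object) {
  z <- object@z
  if (nrow(z) != ncol(z)) return("'z' must be square")
  if (anyNA(z) || any(!is.finite(z))) return("'z' contains non-finite entries")
  if (!isTRUE(all.equal(z, t(z), tolerance = 1e-10))) return("'z' must be symmetric")
  if (any(diag(z) != 0)) return("diagonal of 'z' must be exactly 0")
  if (length(object@regionLabels) != nrow(z))
    return("region labels must match matrix dimension")
  if (anyDuplicated(object@regionLabels)) return("region labels must be unique")
  TRUE
})

#' BinaryNetwork: undirected, unweighted network at a stated density
#'
#' @slot adjacency integer N x N matrix in {0,1}, symmetric, zero diagonal.
#' @slot density fraction of possible edges present, in (0, 1].
#' @slot regionLabels node labels.
#' @export
setClass("BinaryNetwork",
  representation(adjacency = "matrix", density = "numeric",
                 regionLabels = "character"))

setValidity("BinaryNetwork", function(object) {
  a <- object@adjacency
  if (nrow(a) != ncol(a)) return("adjacency must be square")
  if (!all(a %in% c(0L, 1L))) return("adjacency entries must be 0/1")
  if (!identical(unname(a), unname(t(a)))) return("adjacency must be symmetric")
  if (any(diag(a) != 0)) return("self-loops are not allowed")
  if (length(object@regionLabels) != nrow(a))
    return("node labels must match adjacency dimension")
  if (length(object@density) != 1L || object@density < 0 || object@density > 1)
    return("'density' must be a single fraction in [0, 1]")
  TRUE
})

#' MotifCensus: counts of the eight connected undirected 3-4-node motifs
#'
#' @slot counts named numeric vector over the fixed catalogue order.
#' @slot density density of the network the census was taken at (NA if
#'   not applicable).
#' @export
setClass("MotifCensus",
  representation(counts = "numeric", density = "numeric"),
  prototype(density = NA_real_))

setValidity("MotifCensus", function(object) {
  cat_ <- c("path3", "triangle", "path4", "star4", "cycle4", "paw",
            "diamond", "K4")
  if (!identical(names(object@counts), cat_))
    return("counts must be named by the fixed 8-class motif catalogue")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    return("counts must be nonnegative integers")
  TRUE
})

#' NBSResult: supra-threshold components with permutation FWER p-values
#'
#' @slot components list of components, each a list with elements
#'   \code{edges} (two-column label matrix plus t values), \code{nodes},
#'   \code{size} (extent = edge count), \code{intensity} and \code{pFwer};
#'   ordered by decreasing size.
#' @slot tMatrix symmetric edgewise t-statistic matrix.
#' @slot perNodeCounts named counts of altered connections per node,
#'   restricted to significant components.
#' @slot nullMaxSize permutation null distribution of the maximal
#'   component size.
#' @slot config echo of the configuration used (list).
#' @export
setClass("NBSResult",
  representation(components = "list", tMatrix = "matrix",
                 perNodeCounts = "numeric", nullMaxSize = "numeric",
                 config = "list"))

# ---- parameter classes ---------------------------------------------------

#' LatentNetworkSpec: modular latent coupling structure
#'
#' Describes the block (module) structure behind the synthetic covariance:
#' regions are split into near-equal modules; a latent edge exists between
#' a within-module pair with probability \code{pWithin} (weight
#' \code{weightWithin}) and between modules with probability
#' \code{pBetween} (weight \code{weightBetween}). \code{coupling} scales
#' the whole weight matrix after normalization by its baseline spectral
#' radius.
#'
#' @export
setClass("LatentNetworkSpec",
  representation(nNodes = "integer", nModules = "integer",
                 pWithin = "numeric", pBetween = "numeric",
                 coupling = "numeric", weightWithin = "numeric",
                 weightBetween = "numeric", nodeStrengthSd = "numeric",
                 seed = "integer"))

setValidity("LatentNetworkSpec", function(object) {
  if (object@nNodes < 2L) return("'nNodes' must be >= 2")
  if (object@nModules < 1L || object@nModules > object@nNodes)
    return("'nModules' must be between 1 and nNodes")
  if (object@pBetween < 0 || object@pWithin > 1 ||
      object@pBetween > object@pWithin)
    return("need 0 <= pBetween <= pWithin <= 1")
  if (object@coupling < 0) return("'coupling' must be nonnegative")
  if (object@weightWithin <= 0 || object@weightBetween < 0)
    return("latent edge weights must be positive (within) / nonnegative (between)")
  if (object@nodeStrengthSd < 0) return("'nodeStrengthSd' must be >= 0")
  TRUE
})

#' ConditionEffect: planted condition-specific shift of the latent coupling
#'
#' \code{deltaWithin} is added to the within-module weight and
#' \code{deltaBetween} to the between-module weight. A "drug-like" effect
#' (positive \code{deltaWithin}, negative \code{deltaBetween}) strengthens
#' within-module and weakens between-module connectivity, the planted
#' analogue of a shift towards less-integrated, more-segregated topology.
#'
#' @export
setClass("ConditionEffect",
  representation(deltaWithin = "numeric", deltaBetween = "numeric",
                 label = "character"))

setValidity("ConditionEffect", function(object) {
  if (length(object@label) != 1L || !nzchar(object@label))
    return("'label' must be a non-empty string")
  TRUE
})

#' StudyDesignSpec: sampling design of a simulated study
#'
#' @slot design "paired" (two sessions per subject, shared subject effect)
#'   or "two_group" (one session per subject, independent subjects).
#' @slot nSubjects subjects (paired) or subjects per group (two_group).
#' @slot nTimepoints time points per session.
#' @slot samplingInterval seconds between time points.
#' @slot arCoefficient AR(1) coefficient in [0, 1).
#' @slot subjectEffectSd sd of the per-subject lognormal coupling jitter
#'   (paired design; shared across the subject's sessions).
#' @slot seed master seed; per-subject/per-session streams are derived
#'   from it.
#' @export
setClass("StudyDesignSpec",
  representation(design = "character", nSubjects = "integer",
                 nTimepoints = "integer", samplingInterval = "numeric",
                 arCoefficient = "numeric", subjectEffectSd = "numeric",
                 seed = "integer"))

setValidity("StudyDesignSpec", function(object) {
  if (!object@design %in% c("paired", "two_group"))
    return("'design' must be 'paired' or 'two_group'")
  if (object@nSubjects < 1L) return("'nSubjects' must be >= 1")
  if (object@nTimepoints < 1L) return("'nTimepoints' must be >= 1")
  if (object@samplingInterval <= 0) return("'samplingInterval' must be > 0")
  if (object@arCoefficient < 0 || object@arCoefficient >= 1)
    return("'arCoefficient' must be in [0, 1)")
  if (object@subjectEffectSd < 0) return("'subjectEffectSd' must be >= 0")
  TRUE
})

#' NullEnsembleSpec: random reference ensemble for small-worldness
#'
#' @slot nNulls ensemble size (default 100).
#' @slot swapsPerEdge attempted double-edge swaps per edge (default 10).
#' @slot method "rewire_degree_preserving" (Maslov-Sneppen) or
#'   "erdos_renyi_matched".
#' @slot seed RNG seed for the ensemble.
#' @export
setClass("NullEnsembleSpec",
  representation(nNulls = "integer", swapsPerEdge = "integer",
                 method = "character", seed = "integer"))

setValidity("NullEnsembleSpec", function(object) {
  if (object@nNulls < 1L) return("'nNulls' must be >= 1")
  if (object@swapsPerEdge < 1L) return("'swapsPerEdge' must be >= 1")
  if (!object@method %in% c("rewire_degree_preserving", "erdos_renyi_matched"))
    return("unknown null method")
  TRUE
})

#' SweepConfig: density grid and per-density analyses
#'
#' @slot densities strictly increasing grid in (0,1); default 0.05..0.20
#'   in steps of 0.01 (16 levels).
#' @slot nullSpec NullEnsembleSpec used for small-worldness.
#' @slot metrics which metrics to compute.
#' @slot motifs whether to run the motif census per density.
#' @slot rankAbsolute rank edges by |z| instead of signed z.
#' @export
setClass("SweepConfig",
  representation(densities = "numeric", nullSpec = "NullEnsembleSpec",
                 metrics = "character", motifs = "logical",
                 rankAbsolute = "logical"))

setValidity("SweepConfig", function(object) {
  d <- object@densities
  if (length(d) < 1L || any(d <= 0) || any(d >= 1))
    return("densities must lie in (0, 1)")
  if (is.unsorted(d, strictly = TRUE))
    return("densities must be strictly increasing")
  bad <- setdiff(object@metrics, c("C", "L", "Eglob", "Eloc", "sigma"))
  if (length(bad)) return(paste("unknown metrics:", paste(bad, collapse = ", ")))
  TRUE
})

#' NBSConfig: configuration of the Network Based Statistics test
#'
#' The primary threshold on the edgewise t statistic is a required user
#' choice with no default.
#'
#' @export
setClass("NBSConfig",
  representation(primaryThresholdT = "numeric", nPermutations = "integer",
                 alpha = "numeric", tail = "character", design = "character",
                 componentSize = "character", seed = "integer"))

setValidity("NBSConfig", function(object) {
  if (object@primaryThresholdT <= 0) return("'primaryThresholdT' must be > 0")
  if (object@nPermutations < 1L) return("'nPermutations' must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1) return("'alpha' must be in (0, 1)")
  if (!object@tail %in% c("greater", "less", "two_sided"))
    return("'tail' must be greater/less/two_sided")
  if (!object@design %in% c("paired", "two_group"))
    return("'design' must be 'paired' or 'two_group'")
  if (!object@componentSize %in% c("extent", "intensity"))
    return("'componentSize' must be 'extent' or 'intensity'")
  TRUE
})
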