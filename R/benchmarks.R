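# Desk-scale validation studies: directional recovery of the planted
# drug effect, type-I calibration of the AUC t-tests, and FWER
# calibration / power of NBS. These are the package's own reference
# experiments; tests and the acceptance script both call them.

#' The frozen desk-scale benchmark study conditions
#'
#' 60 regions in 5 modules with the package's default latent-network
#' parameters; paired cross-over design with 20 subjects and 300 time
#' points. The drug effect is the default planted one (within-module
#' coupling +0.15, between-module coupling -0.10).
#'
#' @param seed replicate seed; latent pattern and study noise both derive
#'   from it.
#' @param nNodes,nSubjects,nTimepoints overrides.
#' @return list(net, design, placebo, drug).
#' @export
benchmarkStudySpec <- function(seed = 1L, nNodes = 60L, nSubjects = 20L,
                               nTimepoints = 300L) {
  list(net = latentNetworkSpec(nNodes, seed = seed * 2L + 1L),
       design = studyDesignSpec("paired", nSubjects = nSubjects,
                                nTimepoints = nTimepoints, seed = seed * 2L),
       placebo = conditionEffect(0, 0, "placebo"),
       drug = defaultDrugEffect())
}

#' Directional recovery of the planted drug effect
#'
#' Runs replicate benchmark studies end to end (simulation, connectivity,
#' density sweep with small-worldness, motif census, AUC, paired
#' contrasts) and reports, per replicate, the sign of the drug-minus-
#' placebo mean AUC difference for global efficiency, small-worldness and
#' the cyclic-motif total.
#'
#' @param nReplicates number of replicate studies.
#' @param seed base seed; replicate r uses seed + r streams.
#' @param nNulls null-ensemble size for sigma within the sweep (reduced
#'   from the analysis default to keep the benchmark at desk scale).
#' @param nNodes,nSubjects,nTimepoints benchmark overrides.
#' @return data.frame with one row per replicate: mean AUC differences
#'   \code{dEglob}, \code{dSigma}, \code{dCyclic} and the logical
#'   \code{patternHit} (Eglob down, sigma down, cyclic up).
#' @export
recoveryBenchmark <- function(nReplicates = 20L, seed = 1L, nNulls = 6L,
                              nNodes = 60L, nSubjects = 20L,
                              nTimepoints = 300L) {
  rows <- lapply(seq_len(nReplicates), function(r) {
    sp <- benchmarkStudySpec(seed * 1000L + r, nNodes, nSubjects, nTimepoints)
    st <- simulateStudy(sp$design, sp$net, sp$placebo, sp$drug)
    sw <- sweepConfig(nullSpec = nullEnsembleSpec(nNulls = nNulls,
                                                  seed = seed + r))
    res <- analyzeStudy(st$sessions, "paired", sweep = sw)
    tst <- res$tests
    pick <- function(m, fam) tst$mean_diff[tst$metric == m & tst$family == fam]
    dE <- pick("Eglob", "graph_metrics")
    dS <- pick("sigma", "graph_metrics")
    dC <- pick("cyclic", "motif_totals")
    data.frame(replicate = r, dEglob = dE, dSigma = dS, dCyclic = dC,
               patternHit = dE < 0 && dS < 0 && dC > 0)
  })
  do.call(rbind, rows)
}

#' Type-I calibration of the per-metric AUC t-tests
#'
#' Simulates null studies (identical condition effects, so conditions are
#' exchangeable by construction) and records, per graph metric, whether
#' the uncorrected paired t-test on AUC rejects at the given level.
#' Small-worldness is excluded here to keep the replicate count high: its
#' null ensemble dominates runtime and its test statistic is the same
#' paired t on AUC as the other metrics.
#'
#' @param nReplicates number of null studies (hundreds recommended).
#' @param seed base seed.
#' @param alpha nominal level of the uncorrected test.
#' @param nNodes,nSubjects,nTimepoints study size per replicate (reduced
#'   calibration conditions: 60 nodes, n = 12 paired subjects).
#' @return list with \code{rates} (named per-metric rejection rates) and
#'   \code{rejections} (replicates x metrics logical matrix).
#' @export
nullCalibration <- function(nReplicates = 500L, seed = 1L, alpha = 0.05,
                            nNodes = 60L, nSubjects = 12L,
                            nTimepoints = 150L) {
  metrics <- c("C", "L", "Eglob", "Eloc")
  sw <- sweepConfig(metrics = metrics, motifs = FALSE)
  rej <- matrix(NA, nReplicates, length(metrics),
                dimnames = list(NULL, metrics))
  for (r in seq_len(nReplicates)) {
    net <- latentNetworkSpec(nNodes, seed = (seed %% 10000L) * 7919L + r)
    des <- studyDesignSpec("paired", nSubjects = nSubjects,
                           nTimepoints = nTimepoints,
                           seed = (seed %% 10000L) * 104729L %% 1000000L + r)
    st <- simulateStudy(des, net, conditionEffect(0, 0, "placebo"),
                        conditionEffect(0, 0, "drug"))
    res <- analyzeStudy(st$sessions, "paired", sweep = sw)
    tst <- res$tests
    rej[r, ] <- tst$p_raw[match(metrics, tst$metric)] < alpha
  }
  list(rates = colMeans(rej), rejections = rej)
}

#' FWER calibration of NBS on null studies
#'
#' Simulates null paired studies and runs NBS; reports the fraction of
#' studies in which any component reaches p_fwer <= alpha.
#'
#' @param nReplicates number of null studies.
#' @param seed base seed.
#' @param nNodes,nSubjects,nTimepoints study size (defaults follow the
#'   package's reduced calibration conditions: 60 nodes, n = 12).
#' @param nPermutations permutations per study (reduced for calibration).
#' @param thresholdT primary threshold applied to the edgewise t.
#' @param alpha FWER level.
#' @return list with \code{fwer} (scalar rate) and \code{anySignificant}
#'   (logical per replicate).
#' @export
nbsCalibration <- function(nReplicates = 200L, seed = 1L, nNodes = 60L,
                           nSubjects = 12L, nTimepoints = 150L,
                           nPermutations = 500L, thresholdT = 3,
                           alpha = 0.05) {
  hit <- logical(nReplicates)
  for (r in seq_len(nReplicates)) {
    net <- latentNetworkSpec(nNodes, seed = (seed %% 10000L) * 333L + r)
    des <- studyDesignSpec("paired", nSubjects = nSubjects,
                           nTimepoints = nTimepoints,
                           seed = (seed %% 10000L) * 555L + r)
    st <- simulateStudy(des, net, conditionEffect(0, 0, "placebo"),
                        conditionEffect(0, 0, "drug"))
    mats <- lapply(st$sessions, correlationMatrix)
    res <- nbsTest(mats, nbsConfig(primaryThresholdT = thresholdT,
                                   nPermutations = nPermutations,
                                   design = "paired", seed = seed + r))
    ps <- vapply(nbsComponents(res), `[[`, 0, "pFwer")
    hit[r] <- length(ps) > 0 && any(ps <= alpha)
  }
  list(fwer = mean(hit), anySignificant = hit)
}

#' Connectivity stack with a planted differential component
#'
#' Builds paired per-subject Fisher-z matrices: symmetric noise shared
#' within subject plus independent session noise, with a fixed additive
#' shift on a chosen connected edge set in the treatment condition. Used
#' to validate NBS recovery (detection and edge identity).
#'
#' @param nSubjects paired subjects.
#' @param nNodes regions.
#' @param edges two-column index matrix of planted edges (defaults to a
#'   10-edge path over nodes 1..11).
#' @param delta additive z shift on planted edges under the treatment.
#' @param noiseSd sd of the edgewise session noise.
#' @param seed RNG seed.
#' @return list with \code{matrices} (list of
#'   \linkS4class{ConnectivityMatrix}) and \code{edges} (the planted set).
#' @export
plantedComponentStudy <- function(nSubjects = 20L, nNodes = 30L,
                                  edges = cbind(1:10, 2:11), delta = 0.3,
                                  noiseSd = 0.1, seed = 1L) {
  labs <- paste0("R", seq_len(nNodes))
  symNoise <- function(sdv) {
    m <- matrix(rnorm(nNodes * nNodes, 0, sdv), nNodes, nNodes)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  }
  mats <- .withSeed(seed, {
    out <- list()
    for (s in seq_len(nSubjects)) {
      base <- symNoise(noiseSd)
      zp <- base + symNoise(noiseSd / 2)
      zd <- base + symNoise(noiseSd / 2)
      zd[edges] <- zd[edges] + delta
      zd[edges[, 2:1, drop = FALSE]] <- zd[edges]
      sid <- sprintf("S%02d", s)
      out[[2 * s - 1]] <- connectivityMatrix(zp, labs, subjectId = sid,
                                             condition = "placebo")
      out[[2 * s]] <- connectivityMatrix(zd, labs, subjectId = sid,
                                         condition = "drug")
    }
    out
  })
  list(matrices = mats, edges = edges, labels = labs)
}
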