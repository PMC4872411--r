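# Synthetic-data generator: modular latent covariance, AR(1) sessions,
# paired / two-group study simulation, and small fixture graphs.

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so library code never disturbs user RNG.
.withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Near-equal module assignment
#'
#' @param nNodes,nModules counts.
#' @return integer vector of module ids, blocks of near-equal size.
#' @export
moduleAssignment <- function(nNodes, nModules) {
  sort(rep_len(seq_len(nModules), nNodes))
}

# Latent structure shared by both conditions of a study: module labels,
# the sampled edge pattern, and the baseline spectral radius used to
# normalize every effect-adjusted weight matrix.
.latentStructure <- function(spec) {
  n <- spec@nNodes
  mod <- moduleAssignment(n, spec@nModules)
  within <- outer(mod, mod, "==")
  ut <- upper.tri(within)
  draws <- .withSeed(spec@seed, {
    list(u = runif(sum(ut)), s = exp(rnorm(n, 0, spec@nodeStrengthSd)))
  })
  edge <- matrix(FALSE, n, n)
  edge[ut] <- draws$u < ifelse(within[ut], spec@pWithin, spec@pBetween)
  edge <- edge | t(edge)
  hub <- outer(draws$s, draws$s)
  wbase <- matrix(0, n, n)
  wbase[edge & within] <- spec@weightWithin
  wbase[edge & !within] <- spec@weightBetween
  wbase <- wbase * hub
  rho <- if (any(edge)) max(abs(eigen(wbase, symmetric = TRUE,
                                      only.values = TRUE)$values)) else 0
  list(modules = mod, within = within, edge = edge, wbase = wbase,
       hub = hub, rho = rho)
}

#' Build the condition-specific covariance of the latent network
#'
#' Constructs \eqn{\Sigma = I + c\,W/\rho(W_0)} where \eqn{W} is the
#' symmetric latent weight matrix after adding the condition effect's
#' deltas to the within-/between-module weights, and \eqn{\rho(W_0)} is the
#' spectral radius of the baseline (zero-delta) weight matrix. Normalizing
#' by the baseline radius keeps the effect deltas interpretable: a positive
#' \code{deltaWithin} strictly increases every within-module covariance
#' entry. Positive definiteness is verified by eigendecomposition.
#'
#' @param spec a \linkS4class{LatentNetworkSpec}.
#' @param effect a \linkS4class{ConditionEffect}.
#' @param coupling optional override of \code{spec@coupling} (used for the
#'   per-subject jitter in paired designs).
#' @return Symmetric positive-definite covariance matrix with attributes
#'   \code{modules} (module assignment) and \code{withinMask}.
#' @examples
#' sp <- latentNetworkSpec(nNodes = 4, nModules = 1, pWithin = 1,
#'                         pBetween = 1, coupling = 0.5)
#' makeCovariance(sp, conditionEffect())  # equal off-diagonals, PD
#' @export
makeCovariance <- function(spec, effect = conditionEffect(), coupling = NULL) {
  stopifnot(is(spec, "LatentNetworkSpec"), is(effect, "ConditionEffect"))
  validObject(spec); validObject(effect)
  st <- .latentStructure(spec)
  c_ <- if (is.null(coupling)) spec@coupling else coupling
  n <- spec@nNodes
  sigma <- diag(n)
  if (c_ > 0 && st$rho > 0) {
    ww <- max(0, spec@weightWithin + effect@deltaWithin)
    wb <- max(0, spec@weightBetween + effect@deltaBetween)
    w <- matrix(0, n, n)
    w[st$edge & st$within] <- ww
    w[st$edge & !st$within] <- wb
    w <- w * st$hub
    sigma <- sigma + c_ * w / st$rho
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("implied covariance is not positive definite; ",
         "reject this configuration (reduce 'coupling' or the deltas)")
  structure(sigma, modules = st$modules, withinMask = st$within)
}

#' Simulate one session of AR(1) multivariate time series
#'
#' Generates \eqn{x_t = \phi x_{t-1} + \epsilon_t} with
#' \eqn{\epsilon_t \sim N(0, \Sigma)} and a stationary start
#' (\eqn{x_1 \sim N(0, \Sigma/(1-\phi^2))}), so the stationary covariance
#' converges to \eqn{\Sigma/(1-\phi^2)} as T grows. Deterministic given
#' \code{seed}. With short sessions (T not much larger than N) the sample
#' correlation matrix is a noisy estimate of the latent structure; that is
#' intentional, since downstream stages must cope with estimation noise.
#'
#' @param spec a \linkS4class{StudyDesignSpec} (supplies T, TR and phi).
#' @param cov positive-definite innovation covariance.
#' @param seed RNG seed (defaults to the spec's seed).
#' @param subjectId,condition,group metadata attached to the output.
#' @return A \linkS4class{RoiTimeSeries}.
#' @export
simulateSession <- function(spec, cov, seed = spec@seed,
                            subjectId = NA_character_,
                            condition = NA_character_, group = NA_character_) {
  stopifnot(is(spec, "StudyDesignSpec"))
  validObject(spec)
  cov <- unclass(as.matrix(cov))
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("'cov' must be positive definite")
  n <- ncol(cov)
  tt <- spec@nTimepoints
  phi <- spec@arCoefficient
  ch <- chol(cov)
  x <- .withSeed(seed, {
    x1 <- drop(rnorm(n) %*% ch) / sqrt(1 - phi^2)
    if (tt == 1L) {
      matrix(x1, 1L, n)
    } else {
      eps <- matrix(rnorm((tt - 1L) * n), tt - 1L, n) %*% ch
      out <- matrix(0, tt, n)
      out[1L, ] <- x1
      if (phi == 0) {
        out[-1L, ] <- eps
      } else {
        for (j in seq_len(n))
          out[-1L, j] <- stats::filter(eps[, j], phi, method = "recursive",
                                       init = x1[j])
      }
      out
    }
  })
  roiTimeSeries(x, samplingInterval = spec@samplingInterval,
                subjectId = subjectId, condition = condition, group = group)
}

#' Simulate a full labelled study
#'
#' Paired design: each subject contributes one session per condition; a
#' per-subject multiplicative lognormal jitter on the latent coupling is
#' shared across the subject's sessions, so paired contrasts gain power
#' over unpaired ones (the cross-over rationale). Two-group design: one
#' session per subject, \code{nSubjects} per condition, independent
#' subjects. All randomness flows from the design's master seed: subject
#' jitters and per-session seeds are drawn once from it and recorded in
#' the manifest, so any single session can be regenerated in isolation.
#'
#' @param design a \linkS4class{StudyDesignSpec}.
#' @param net a \linkS4class{LatentNetworkSpec}.
#' @param placebo,drug \linkS4class{ConditionEffect}s for the two
#'   conditions.
#' @return list with \code{sessions} (list of \linkS4class{RoiTimeSeries}),
#'   \code{manifest} (data.frame: subject_id, condition, group, seed) and
#'   \code{config} (echo of the generating parameters).
#' @export
simulateStudy <- function(design, net,
                          placebo = conditionEffect(0, 0, "placebo"),
                          drug = conditionEffect(0, 0, "drug")) {
  stopifnot(is(design, "StudyDesignSpec"), is(net, "LatentNetworkSpec"))
  validObject(design); validObject(net)
  ns <- design@nSubjects
  paired <- design@design == "paired"
  nSess <- if (paired) 2L * ns else 2L * ns  # two_group: ns per group
  draws <- .withSeed(design@seed, {
    list(jitter = rnorm(if (paired) ns else 2L * ns, 0, design@subjectEffectSd),
         seeds = sample.int(2147483646L, nSess))
  })
  sessions <- vector("list", nSess)
  manifest <- data.frame(subject_id = character(nSess),
                         condition = character(nSess),
                         group = character(nSess),
                         seed = integer(nSess),
                         stringsAsFactors = FALSE)
  k <- 0L
  if (paired) {
    for (s in seq_len(ns)) {
      cs <- net@coupling * exp(draws$jitter[s])
      for (eff in list(placebo, drug)) {
        k <- k + 1L
        covm <- makeCovariance(net, eff, coupling = cs)
        sid <- sprintf("S%02d", s)
        sessions[[k]] <- simulateSession(design, covm, seed = draws$seeds[k],
                                         subjectId = sid,
                                         condition = eff@label,
                                         group = "crossover")
        manifest[k, ] <- list(sid, eff@label, "crossover", draws$seeds[k])
      }
    }
  } else {
    effs <- list(placebo, drug)
    for (g in 1:2) {
      for (s in seq_len(ns)) {
        k <- k + 1L
        idx <- (g - 1L) * ns + s
        cs <- net@coupling * exp(draws$jitter[idx])
        covs <- makeCovariance(net, effs[[g]], coupling = cs)
        sid <- sprintf("S%02d", idx)
        sessions[[k]] <- simulateSession(design, covs, seed = draws$seeds[k],
                                         subjectId = sid,
                                         condition = effs[[g]]@label,
                                         group = effs[[g]]@label)
        manifest[k, ] <- list(sid, effs[[g]]@label, effs[[g]]@label,
                              draws$seeds[k])
      }
    }
  }
  cfg <- list(design = design@design, n_subjects = ns,
              n_timepoints = design@nTimepoints,
              sampling_interval = design@samplingInterval,
              ar_coefficient = design@arCoefficient,
              subject_effect_sd = design@subjectEffectSd,
              master_seed = design@seed,
              n_nodes = net@nNodes, n_modules = net@nModules,
              p_within = net@pWithin, p_between = net@pBetween,
              coupling = net@coupling,
              weight_within = net@weightWithin,
              weight_between = net@weightBetween,
              latent_seed = net@seed,
              placebo = list(delta_within = placebo@deltaWithin,
                             delta_between = placebo@deltaBetween),
              drug = list(delta_within = drug@deltaWithin,
                          delta_between = drug@deltaBetween))
  list(sessions = sessions, manifest = manifest, config = cfg)
}

#' The default planted "drug-like" condition effect
#'
#' Within-module coupling up, between-module coupling down: the planted
#' analogue of a shift towards less-integrated, more-segregated topology.
#'
#' @export
defaultDrugEffect <- function() conditionEffect(0.15, -0.10, "drug")

# internal: BinaryNetwork from an explicit edge list
.bnFromEdges <- function(n, edges, labels = paste0("N", seq_len(n))) {
  a <- matrix(0L, n, n)
  if (length(edges)) {
    e <- if (is.matrix(edges)) edges
         else matrix(as.integer(edges), ncol = 2, byrow = TRUE)
    storage.mode(e) <- "integer"
    a[e] <- 1L
    a[e[, 2:1, drop = FALSE]] <- 1L
  }
  binaryNetwork(a, regionLabels = labels)
}

#' Named fixture graphs with known structure
#'
#' Small graphs whose metric and motif values are known in closed form,
#' plus a 30-node ring lattice (each node linked to its two nearest
#' neighbours on each side) and a seeded Erdos-Renyi G(30, 0.2) graph.
#'
#' @param erSeed seed for the Erdos-Renyi fixture (fixed default so the
#'   fixture is reproducible across calls).
#' @return Named list of \linkS4class{BinaryNetwork}s: triangle, path3,
#'   path4, star4, cycle4, paw, diamond, K4, K5, twoTriangles (10 nodes,
#'   disconnected), ringLattice (30, k = 4), erdosRenyi (30, 0.2).
#' @export
fixtureGraphs <- function(erSeed = 42L) {
  g <- list()
  g$triangle <- .bnFromEdges(3, c(1,2, 2,3, 1,3))
  g$path3    <- .bnFromEdges(3, c(1,2, 2,3))
  g$path4    <- .bnFromEdges(4, c(1,2, 2,3, 3,4))
  g$star4    <- .bnFromEdges(4, c(1,2, 1,3, 1,4))
  g$cycle4   <- .bnFromEdges(4, c(1,2, 2,3, 3,4, 1,4))
  g$paw      <- .bnFromEdges(4, c(1,2, 2,3, 1,3, 3,4))
  g$diamond  <- .bnFromEdges(4, c(1,2, 2,3, 3,4, 1,4, 1,3))
  g$K4       <- .bnFromEdges(4, t(combn(4, 2)))
  g$K5       <- .bnFromEdges(5, t(combn(5, 2)))
  g$twoTriangles <- .bnFromEdges(10, c(1,2, 2,3, 1,3, 4,5, 5,6, 4,6))
  ring <- matrix(0L, 30, 30)
  for (i in 1:30) for (d in 1:2) {
    j <- ((i - 1 + d) %% 30) + 1
    ring[i, j] <- ring[j, i] <- 1L
  }
  g$ringLattice <- binaryNetwork(ring)
  er <- matrix(0L, 30, 30)
  .withSeed(erSeed, {
    ut <- which(upper.tri(er))
    er[ut] <- as.integer(runif(length(ut)) < 0.2)
  })
  er <- er + t(er)
  g$erdosRenyi <- binaryNetwork(er)
  g
}
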