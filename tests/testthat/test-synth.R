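# Synthetic-data generator: covariance construction, AR(1) sessions,
# study bookkeeping, fixture graphs.

test_that("zero coupling gives the identity covariance", {
  sp <- latentNetworkSpec(5, 1, coupling = 0)
  S <- makeCovariance(sp, conditionEffect())
  expect_equal(unclass(S)[seq_len(25)], as.vector(diag(5)))
})

test_that("one dense module gives equal off-diagonals and a PD matrix", {
  sp <- latentNetworkSpec(4, 1, pWithin = 1, pBetween = 1, coupling = 0.5,
                          nodeStrengthSd = 0)
  S <- makeCovariance(sp, conditionEffect())
  off <- S[upper.tri(S)]
  expect_true(all(abs(off - off[1]) < 1e-12))
  ev <- eigen(unclass(S), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("a positive within-module delta strictly raises within entries", {
  sp <- latentNetworkSpec(4, 1, pWithin = 1, pBetween = 1, coupling = 0.5,
                          nodeStrengthSd = 0)
  S0 <- makeCovariance(sp, conditionEffect(0, 0))
  S1 <- makeCovariance(sp, conditionEffect(0.2, 0, "drug"))
  expect_true(all(S1[upper.tri(S1)] > S0[upper.tri(S0)]))
})

test_that("non-positive-definite configurations are rejected", {
  sp <- latentNetworkSpec(6, 1, pWithin = 1, pBetween = 1, coupling = 0.9,
                          nodeStrengthSd = 0)
  # a large negative within delta cannot break PD (weights floor at 0),
  # but a coupling far above 1 with negative eigenvalues must error
  sp2 <- latentNetworkSpec(6, 3, pWithin = 1, pBetween = 0.5, coupling = 4,
                           nodeStrengthSd = 0)
  expect_error(makeCovariance(sp2, conditionEffect()), "positive definite")
  expect_silent(makeCovariance(sp, conditionEffect()))
})

test_that("simulated sessions are deterministic given the seed", {
  sp <- latentNetworkSpec(6, 2, seed = 3)
  S <- makeCovariance(sp, conditionEffect())
  des <- studyDesignSpec("paired", nSubjects = 2, nTimepoints = 40, seed = 9)
  a <- simulateSession(des, S, seed = 11)
  b <- simulateSession(des, S, seed = 11)
  expect_identical(tsMatrix(a), tsMatrix(b))
  c2 <- simulateSession(des, S, seed = 12)
  expect_false(identical(tsMatrix(a), tsMatrix(c2)))
})

test_that("a single-time-point session is valid output", {
  des <- studyDesignSpec("paired", nSubjects = 1, nTimepoints = 1, seed = 1)
  ts <- simulateSession(des, diag(4), seed = 2)
  expect_identical(dim(tsMatrix(ts)), c(1L, 4L))
})

test_that("white-noise sessions have near-zero cross-correlations", {
  des <- studyDesignSpec("paired", nSubjects = 1, nTimepoints = 50000,
                         arCoefficient = 0, seed = 1)
  ts <- simulateSession(des, diag(4), seed = 5)
  r <- cor(tsMatrix(ts))
  expect_lt(max(abs(r[upper.tri(r)])), 0.02)
})

test_that("sample covariance converges to cov/(1 - phi^2) as T grows", {
  sp <- latentNetworkSpec(5, 1, pWithin = 1, pBetween = 1, coupling = 0.5,
                          nodeStrengthSd = 0, seed = 2)
  S <- unclass(makeCovariance(sp, conditionEffect()))
  phi <- 0.3
  target <- S / (1 - phi^2)
  err <- vapply(c(500, 5000, 50000), function(tt) {
    des <- studyDesignSpec("paired", nSubjects = 1, nTimepoints = tt,
                           arCoefficient = phi, seed = 1)
    x <- tsMatrix(simulateSession(des, S, seed = 42))
    norm(cov(x) - target, "F")
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.05)
})

test_that("paired studies emit two sessions per subject with shared ids", {
  st <- simulateStudy(studyDesignSpec("paired", nSubjects = 3,
                                      nTimepoints = 20, seed = 4),
                      latentNetworkSpec(10, 2, seed = 1))
  expect_length(st$sessions, 6)
  expect_identical(st$manifest$subject_id,
                   rep(sprintf("S%02d", 1:3), each = 2))
  expect_identical(st$manifest$condition, rep(c("placebo", "drug"), 3))
})

test_that("two-group studies emit n sessions per group", {
  st <- simulateStudy(studyDesignSpec("two_group", nSubjects = 9,
                                      nTimepoints = 20, seed = 4),
                      latentNetworkSpec(10, 2, seed = 1))
  expect_length(st$sessions, 18)
  expect_identical(as.vector(table(st$manifest$condition)[c("placebo", "drug")]),
                   c(9L, 9L))
  expect_identical(anyDuplicated(st$manifest$subject_id), 0L)
})

test_that("the study manifest makes single sessions reproducible in isolation", {
  net <- latentNetworkSpec(8, 2, seed = 7)
  des <- studyDesignSpec("paired", nSubjects = 2, nTimepoints = 30, seed = 13)
  st <- simulateStudy(des, net, conditionEffect(), defaultDrugEffect())
  # rebuild session 4 (subject 2, drug) from the manifest seed alone
  jit <- netpharm:::.withSeed(des@seed, rnorm(2, 0, des@subjectEffectSd))
  covm <- makeCovariance(net, defaultDrugEffect(),
                         coupling = net@coupling * exp(jit[2]))
  rebuilt <- simulateSession(des, covm, seed = st$manifest$seed[4])
  expect_identical(tsMatrix(rebuilt), tsMatrix(st$sessions[[4]]))
})

test_that("fixture graphs have their defining structure", {
  g <- fixtureGraphs()
  expect_identical(edgeCount(g$K4), 6L)
  expect_identical(unname(rowSums(adjacencyMatrix(g$cycle4))),
                   rep(2, 4))
  expect_identical(edgeCount(g$K5), 10L)
  expect_identical(nrow(adjacencyMatrix(g$twoTriangles)), 10L)
  expect_identical(unname(rowSums(adjacencyMatrix(g$ringLattice))),
                   rep(4, 30))
  expect_identical(adjacencyMatrix(g$erdosRenyi),
                   adjacencyMatrix(fixtureGraphs()$erdosRenyi))
})
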