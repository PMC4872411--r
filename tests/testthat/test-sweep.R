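# Density sweep, AUC summarization, group tests and FDR.

mkSymZ <- function(n, seed) {
  set.seed(seed)
  z <- matrix(rnorm(n * n, 0, 0.3), n, n)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  z
}

test_that("the default grid yields 16 values per metric", {
  cm <- connectivityMatrix(mkSymZ(20, 1), subjectId = "S1",
                           condition = "placebo")
  sw <- sweepMetrics(cm, sweepConfig(nullSpec = nullEnsembleSpec(nNulls = 3)))
  expect_identical(nrow(sw$metrics), 16L * 5L)
  expect_identical(sort(unique(sw$metrics$density)),
                   seq(0.05, 0.20, by = 0.01))
  expect_identical(sum(sw$metrics$metric == "Eglob"), 16L)
})

test_that("Eglob is non-decreasing across the nested density grid", {
  for (s in 1:4) {
    cm <- connectivityMatrix(mkSymZ(25, s))
    sw <- sweepMetrics(cm, sweepConfig(metrics = "Eglob", motifs = FALSE))
    eg <- sw$metrics$value[sw$metrics$metric == "Eglob"]
    expect_true(all(diff(eg) >= 0))
  }
})

test_that("identical inputs give identical curves", {
  cm <- connectivityMatrix(mkSymZ(20, 7))
  cfg <- sweepConfig(nullSpec = nullEnsembleSpec(nNulls = 4, seed = 5))
  expect_identical(sweepMetrics(cm, cfg), sweepMetrics(cm, cfg))
})

test_that("AUC has its closed forms and matches a numerical oracle", {
  d <- seq(0.05, 0.20, by = 0.01)
  expect_equal(aucCurve(rep(1, 16), d), 0.15, tolerance = 1e-12)
  expect_equal(aucCurve(seq(0, 1, length.out = 16), d), 0.075,
               tolerance = 1e-12)
  skip_if_not_installed("pracma")
  set.seed(2)
  for (i in 1:5) {
    y <- rnorm(16)
    expect_equal(aucCurve(y, d), pracma::trapz(d, y), tolerance = 1e-12)
  }
})

test_that("AUC is linear and rejects missing values with densities named", {
  d <- seq(0.05, 0.20, by = 0.01)
  set.seed(3)
  f <- rnorm(16); g <- rnorm(16)
  expect_equal(aucCurve(2 * f + 3 * g, d),
               2 * aucCurve(f, d) + 3 * aucCurve(g, d), tolerance = 1e-12)
  bad <- f; bad[c(2, 5)] <- NA
  expect_error(aucCurve(bad, d), "0.06.*0.09")
  expect_error(aucCurve(1, 0.05), "2 grid points")
})

mkAucTable <- function(vals, design = "paired") {
  if (design == "paired") {
    n <- length(vals$placebo)
    data.frame(subject_id = rep(sprintf("S%d", 1:n), 2),
               condition = rep(c("placebo", "drug"), each = n),
               group = "crossover", metric = "Eglob",
               auc = c(vals$placebo, vals$drug), stringsAsFactors = FALSE)
  } else {
    data.frame(subject_id = sprintf("S%d", seq_along(c(vals$placebo, vals$drug))),
               condition = rep(c("placebo", "drug"),
                               c(length(vals$placebo), length(vals$drug))),
               group = rep(c("placebo", "drug"),
                           c(length(vals$placebo), length(vals$drug))),
               metric = "Eglob",
               auc = c(vals$placebo, vals$drug), stringsAsFactors = FALSE)
  }
}

test_that("paired t on all-zero differences is t = 0, p = 1", {
  x <- rnorm(6)
  res <- groupTest(mkAucTable(list(placebo = x, drug = x)), "paired")
  expect_identical(res$t, 0)
  expect_identical(res$p_raw, 1)
  expect_identical(res$df, 5)
})

test_that("constant nonzero differences are a degenerate-input error", {
  x <- rnorm(4)
  expect_error(groupTest(mkAucTable(list(placebo = x, drug = x + 1)), "paired"),
               "zero-variance")
})

test_that("paired and two-group tests match stats::t.test", {
  set.seed(8)
  p <- rnorm(10); dr <- rnorm(10, 0.3)
  res <- groupTest(mkAucTable(list(placebo = p, drug = dr)), "paired")
  ref <- t.test(dr - p)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_raw, ref$p.value, tolerance = 1e-12)
  expect_identical(res$df, 9)
  res2 <- groupTest(mkAucTable(list(placebo = p, drug = dr), "two_group"),
                    "two_group")
  ref2 <- t.test(dr, p, var.equal = TRUE)
  expect_equal(res2$t, unname(ref2$statistic), tolerance = 1e-12)
  expect_equal(res2$p_raw, ref2$p.value, tolerance = 1e-12)
  expect_identical(res2$df, 18)
})

test_that("unpairable subjects are named in the error", {
  tab <- mkAucTable(list(placebo = rnorm(3), drug = rnorm(3)))
  tab <- tab[tab$subject_id != "S2" | tab$condition != "drug", ]
  expect_error(groupTest(tab, "paired"), "S2")
})

test_that("null p-values are uniform over simulated replicates", {
  set.seed(13)
  ps <- replicate(1000, {
    x <- rnorm(8); y <- rnorm(8)
    groupTest(mkAucTable(list(placebo = x, drug = y)), "paired")$p_raw
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH adjustment follows the step-up construction", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5),
               tolerance = 1e-12)
  expect_identical(fdrAdjust(0.37), 0.37)
  expect_identical(fdrAdjust(rep(0.2, 4)), rep(0.2, 4))
  expect_error(fdrAdjust(c(0.1, 1.2)), "outside")
  # independent hand construction on a random vector
  set.seed(4)
  p <- runif(7)
  m <- length(p)
  o <- order(p)
  stepup <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  expect_equal(fdrAdjust(p)[o], stepup, tolerance = 1e-12)
})

test_that("a toy paired analysis emits complete, consistent test tables", {
  net <- latentNetworkSpec(16, 2, seed = 3)
  des <- studyDesignSpec("paired", nSubjects = 3, nTimepoints = 60, seed = 5)
  st <- simulateStudy(des, net, conditionEffect(), defaultDrugEffect())
  res <- analyzeStudy(st$sessions, "paired",
                      sweep = sweepConfig(densities = seq(0.2, 0.4, 0.05),
                                          nullSpec = nullEnsembleSpec(nNulls = 3)))
  tst <- res$tests
  expect_identical(sum(tst$family == "graph_metrics"), 5L)
  expect_identical(sum(tst$family == "motifs"), 8L)
  expect_identical(sum(tst$family == "motif_totals"), 2L)
  expect_true(all(tst$p_fdr >= tst$p_raw - 1e-12))
  expect_true(all(tst$p_fdr >= 0 & tst$p_fdr <= 1))
  expect_identical(tst$df[tst$family == "graph_metrics"], rep(2, 5))
})

test_that("identical sessions across conditions give all-null tests", {
  net <- latentNetworkSpec(12, 2, seed = 2)
  des <- studyDesignSpec("paired", nSubjects = 3, nTimepoints = 50, seed = 8)
  covm <- makeCovariance(net, conditionEffect())
  sessions <- list()
  for (s in 1:3) {
    ts <- simulateSession(des, covm, seed = 100 + s,
                          subjectId = sprintf("S%d", s))
    for (cond in c("placebo", "drug")) {
      tsc <- ts
      tsc@condition <- cond
      sessions[[length(sessions) + 1]] <- tsc
    }
  }
  res <- analyzeStudy(sessions, "paired",
                      sweep = sweepConfig(densities = c(0.25, 0.35),
                                          metrics = c("C", "L", "Eglob", "Eloc"),
                                          motifs = TRUE))
  expect_true(all(res$tests$t == 0))
  expect_true(all(res$tests$p_raw == 1))
})
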