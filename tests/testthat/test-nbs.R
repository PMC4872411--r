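# Network Based Statistics: edgewise t, components, permutation FWER.

mkStack <- function(nSubjects, nNodes, seed, shift = NULL, delta = 0) {
  set.seed(seed)
  labs <- paste0("R", seq_len(nNodes))
  mats <- list()
  for (s in seq_len(nSubjects)) {
    for (cond in c("placebo", "drug")) {
      z <- matrix(rnorm(nNodes^2, 0, 0.2), nNodes, nNodes)
      z <- (z + t(z)) / 2; diag(z) <- 0
      if (cond == "drug" && !is.null(shift)) {
        z[shift] <- z[shift] + delta
        z[shift[, 2:1, drop = FALSE]] <- z[shift]
      }
      mats[[length(mats) + 1]] <- connectivityMatrix(
        z, labs, subjectId = sprintf("S%02d", s), condition = cond)
    }
  }
  mats
}

test_that("edgewise paired t equals a looped scalar t-test oracle", {
  mats <- mkStack(8, 10, seed = 1)
  tm <- edgewiseT(mats, "paired")
  expect_identical(attr(tm, "df"), 7)
  idx <- which(vapply(mats, function(m) m@condition == "placebo", TRUE))
  for (pair in list(c(1, 2), c(3, 9), c(5, 10))) {
    d <- vapply(seq(1, 16, by = 2), function(k)
      zMatrix(mats[[k + 1]])[pair[1], pair[2]] -
        zMatrix(mats[[k]])[pair[1], pair[2]], 0)
    expect_equal(tm[pair[1], pair[2]], unname(t.test(d)$statistic),
                 tolerance = 1e-12)
  }
  expect_identical(unname(diag(tm)), rep(0, 10))
  expect_identical(unname(tm), unname(t(tm)))
})

test_that("edgewise two-group t equals the pooled t-test oracle", {
  mats <- mkStack(6, 8, seed = 2)
  tm <- edgewiseT(mats, "two_group")
  expect_identical(attr(tm, "df"), 10)
  a <- sapply(mats[vapply(mats, function(m) m@condition == "placebo", TRUE)],
              function(m) zMatrix(m)[2, 5])
  b <- sapply(mats[vapply(mats, function(m) m@condition == "drug", TRUE)],
              function(m) zMatrix(m)[2, 5])
  expect_equal(tm[2, 5], unname(t.test(b, a, var.equal = TRUE)$statistic),
               tolerance = 1e-12)
})

test_that("identical conditions give an all-zero t matrix", {
  set.seed(3)
  labs <- paste0("R", 1:6)
  mats <- list()
  for (s in 1:5) {
    z <- matrix(rnorm(36, 0, 0.2), 6, 6); z <- (z + t(z)) / 2; diag(z) <- 0
    for (cond in c("placebo", "drug"))
      mats[[length(mats) + 1]] <- connectivityMatrix(
        z, labs, subjectId = sprintf("S%d", s), condition = cond)
  }
  tm <- suppressWarnings(edgewiseT(mats, "paired"))
  expect_true(all(tm == 0))
})

test_that("a consistently shifted edge attains the maximal |t|", {
  shift <- matrix(c(3L, 7L), 1)
  mats <- mkStack(12, 10, seed = 4, shift = shift, delta = 0.6)
  tm <- edgewiseT(mats, "paired")
  expect_equal(max(abs(tm)), tm[3, 7], tolerance = 1e-12)
})

test_that("supra-threshold components are found by extent", {
  tm <- matrix(0, 8, 8)
  # planted 5-edge star at node 1 (nodes 1-6)
  for (j in 2:6) tm[1, j] <- tm[j, 1] <- 5
  comps <- supraThresholdComponents(tm, 4)
  expect_length(comps, 1)
  expect_identical(comps[[1]]$size, 5L)
  expect_length(comps[[1]]$nodes, 6)
  # all below threshold -> empty
  expect_length(supraThresholdComponents(tm, 6), 0)
  # two disjoint paths
  tm2 <- matrix(0, 10, 10)
  for (e in list(c(1,2), c(2,3), c(3,4), c(6,7), c(7,8)))
    tm2[e[1], e[2]] <- tm2[e[2], e[1]] <- 3
  comps2 <- supraThresholdComponents(tm2, 2.5)
  expect_identical(unname(vapply(comps2, `[[`, 0L, "size")), c(3L, 2L))
})

test_that("component extent is monotone non-increasing in the threshold", {
  set.seed(5)
  tm <- matrix(rnorm(400), 20, 20); tm <- (tm + t(tm)) / 2; diag(tm) <- 0
  sizes <- vapply(c(0.5, 1, 1.5, 2), function(thr) {
    comps <- supraThresholdComponents(tm, thr)
    if (length(comps)) comps[[1]]$size else 0L
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("nbsTest recovers a planted component and controls p", {
  ps <- plantedComponentStudy(nSubjects = 20, seed = 31)
  res <- nbsTest(ps$matrices, nbsConfig(primaryThresholdT = 4,
                                        nPermutations = 1000,
                                        design = "paired", seed = 7))
  comps <- nbsComponents(res)
  expect_gte(length(comps), 1)
  top <- comps[[1]]
  expect_lte(top$pFwer, 0.05)
  expect_gte(top$pFwer, 1 / 1001)  # add-one convention: p > 0
  rec <- paste(pmin(match(top$edges$from, ps$labels),
                    match(top$edges$to, ps$labels)),
               pmax(match(top$edges$from, ps$labels),
                    match(top$edges$to, ps$labels)))
  truth <- paste(ps$edges[, 1], ps$edges[, 2])
  jac <- length(intersect(rec, truth)) / length(union(rec, truth))
  expect_gte(jac, 0.8)
})

test_that("per-node altered-connection counts satisfy the handshake lemma", {
  ps <- plantedComponentStudy(nSubjects = 20, seed = 32)
  res <- nbsTest(ps$matrices, nbsConfig(primaryThresholdT = 4,
                                        nPermutations = 500,
                                        design = "paired", seed = 8))
  cnt <- alteredConnectionCounts(res)
  sig <- Filter(function(comp) comp$pFwer <= 0.05, nbsComponents(res))
  expect_identical(sum(cnt), 2 * sum(vapply(sig, `[[`, 0L, "size")))
  # path interior nodes have 2 altered connections, endpoints 1
  expect_identical(unname(sort(cnt, decreasing = TRUE)[1]), 2)
})

test_that("small paired samples warn about the achievable minimum p", {
  ps <- plantedComponentStudy(nSubjects = 3, seed = 33)
  expect_warning(
    nbsTest(ps$matrices, nbsConfig(primaryThresholdT = 4, nPermutations = 200,
                                   design = "paired", seed = 9)),
    "minimum achievable p|sign patterns")
})

test_that("exhaustive sign enumeration is used when 2^n fits the budget", {
  ps <- plantedComponentStudy(nSubjects = 8, seed = 34)
  expect_message(
    res <- nbsTest(ps$matrices, nbsConfig(primaryThresholdT = 4,
                                          nPermutations = 500,
                                          design = "paired", seed = 10)),
    "full enumeration")
  expect_identical(length(res@nullMaxSize), 256L)
})

test_that("two-sided NBS Bonferroni-corrects across tails", {
  ps <- plantedComponentStudy(nSubjects = 15, delta = -0.4, seed = 35)
  res <- nbsTest(ps$matrices, nbsConfig(primaryThresholdT = 3.5,
                                        nPermutations = 300,
                                        tail = "two_sided",
                                        design = "paired", seed = 11))
  comps <- nbsComponents(res)
  expect_true(any(vapply(comps, `[[`, "", "tail") == "less"))
  expect_true(all(vapply(comps, `[[`, 0, "pFwer") >= 2 / 301 - 1e-12))
})

test_that("configuration invariants are enforced", {
  expect_error(nbsConfig(), "required")
  expect_error(nbsConfig(primaryThresholdT = -1), "primaryThresholdT")
  expect_error(nbsConfig(primaryThresholdT = 3, alpha = 1.5), "alpha")
})
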