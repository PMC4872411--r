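# Band-pass filtering, Fisher-z correlation, proportional thresholding.

fftAmplitude <- function(x, freqHz, tr) {
  n <- length(x)
  f <- (seq_len(n) - 1) / (n * tr)
  sp <- abs(fft(x)) / n * 2
  sp[which.min(abs(f - freqHz))]
}

test_that("band-pass preserves in-band sines and attenuates out-of-band ones", {
  tr <- 1.79
  tt <- (0:511) * tr
  fIn <- 46 / (512 * tr)    # ~0.050 Hz, aligned to an FFT bin
  fOut <- 230 / (512 * tr)  # ~0.251 Hz
  inband <- sin(2 * pi * fIn * tt)
  outband <- sin(2 * pi * fOut * tt)
  ts <- roiTimeSeries(cbind(inband, outband), c("in", "out"),
                      samplingInterval = tr)
  filt <- bandpass(ts, 0.01, 0.15)
  a_in <- fftAmplitude(tsMatrix(filt)[, "in"], fIn, tr)
  a_out <- fftAmplitude(tsMatrix(filt)[, "out"], fOut, tr)
  expect_gt(a_in, 0.95)
  expect_lt(a_in, 1.05)
  expect_lt(a_out, 0.1)   # >= 90% attenuation
})

test_that("a constant region filters to all zeros", {
  ts <- roiTimeSeries(cbind(rep(5, 100), rnorm(100)), c("const", "noise"),
                      samplingInterval = 2)
  filt <- bandpass(ts, 0.01, 0.1)
  expect_lt(max(abs(tsMatrix(filt)[, "const"])), 1e-8)
})

test_that("bands beyond Nyquist are rejected naming the bound", {
  ts <- roiTimeSeries(matrix(rnorm(200), 100, 2), samplingInterval = 4)
  expect_error(bandpass(ts, 0.01, 0.15), "Nyquist")
})

test_that("correlation matrices match a two-pass covariance oracle", {
  set.seed(31)
  for (i in 1:5) {
    x <- matrix(rnorm(200), 40, 5)
    cm <- correlationMatrix(roiTimeSeries(x))
    # independent oracle: explicit two-pass covariance then normalization
    xc <- sweep(x, 2, colMeans(x))
    cv <- crossprod(xc) / (nrow(x) - 1)
    r <- cv / sqrt(outer(diag(cv), diag(cv)))
    zo <- atanh(r)
    diag(zo) <- 0
    expect_equal(unname(zMatrix(cm)), unname(zo), tolerance = 1e-12)
  }
})

test_that("known correlations give the expected Fisher z", {
  # orthogonal sinusoids: r = 0 exactly => z = 0
  tt <- seq_len(64)
  x <- cbind(sin(2 * pi * tt / 16), cos(2 * pi * tt / 16))
  cm <- correlationMatrix(roiTimeSeries(x))
  expect_equal(zMatrix(cm)[1, 2], 0, tolerance = 1e-10)
  # constructed pair with r = 0.5 exactly: b = 0.5 a + sqrt(0.75) y with
  # y orthogonal to a and of equal norm
  a <- rep(c(1, -1), 32)
  y <- rep(c(1, 1, -1, -1), 16)
  b <- 0.5 * a + sqrt(0.75) * y
  r <- cor(a, b)
  expect_equal(r, 0.5, tolerance = 1e-12)
  cm2 <- correlationMatrix(roiTimeSeries(cbind(a, b)))
  expect_equal(cm2@z[1, 2], atanh(0.5), tolerance = 1e-12)
  expect_equal(cm2@z[1, 2], 0.5493, tolerance = 1e-4)
})

test_that("independent long noise series give near-zero z", {
  set.seed(7)
  x <- matrix(rnorm(20000), 10000, 2)
  cm <- correlationMatrix(roiTimeSeries(x))
  expect_lt(abs(cm@z[1, 2]), 0.05)
})

test_that("degenerate inputs are rejected with the offending region named", {
  x <- cbind(A = rep(1, 10), B = rnorm(10))
  expect_error(correlationMatrix(roiTimeSeries(x)), "zero-variance.*A")
  y <- rnorm(10)
  expect_error(correlationMatrix(roiTimeSeries(cbind(P = y, Q = 2 * y))),
               "\\|r\\| = 1.*P~Q")
  expect_error(correlationMatrix(roiTimeSeries(matrix(rnorm(4), 2, 2))),
               "3 time points")
})

test_that("proportional thresholding keeps exactly k top edges", {
  z <- matrix(0, 4, 4)
  z[upper.tri(z)] <- c(0.9, 0.7, 0.5, 0.3, 0.2, 0.1)
  z <- z + t(z)
  cm <- connectivityMatrix(z)
  g <- thresholdProportional(cm, 0.5)  # k = round(0.5 * 6) = 3
  expect_identical(edgeCount(g), 3L)
  a <- adjacencyMatrix(g)
  expect_identical(unname(a[1, 2] + a[1, 3] + a[2, 3]), 3L)
})

test_that("near-unit density gives the complete graph and k bounds error", {
  set.seed(2)
  z <- matrix(rnorm(100), 10, 10)
  z <- (z + t(z)) / 2; diag(z) <- 0
  cm <- connectivityMatrix(z)
  g <- thresholdProportional(cm, 0.999)
  expect_identical(edgeCount(g), 45L)
  expect_error(thresholdProportional(cm, 0.005), "k = 0")
})

test_that("ties at the cutoff warn and break deterministically", {
  z <- matrix(0.5, 4, 4); diag(z) <- 0
  cm <- connectivityMatrix(z)
  expect_warning(g <- thresholdProportional(cm, 1 / 3), "ties")  # k = 2
  a <- adjacencyMatrix(g)
  # lexicographic (row, col): edges (1,2) and (1,3)
  expect_identical(unname(a[1, 2]), 1L)
  expect_identical(unname(a[1, 3]), 1L)
  expect_identical(edgeCount(g), 2L)
})

test_that("edge counts are exact and edge sets nest across densities", {
  set.seed(11)
  for (i in 1:5) {
    n <- 20
    z <- matrix(rnorm(n * n), n, n)
    z <- (z + t(z)) / 2; diag(z) <- 0
    cm <- connectivityMatrix(z)
    prev <- NULL
    for (d in c(0.05, 0.1, 0.15, 0.2, 0.4)) {
      g <- thresholdProportional(cm, d)
      expect_identical(edgeCount(g), as.integer(round(d * n * (n - 1) / 2)))
      cur <- which(adjacencyMatrix(g) == 1L)
      if (!is.null(prev)) expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("round-half-even rounding fixes the edge count reproducibly", {
  # 9 nodes: 36 pairs; d = 0.125 -> 4.5 -> round-half-even = 4
  set.seed(3)
  z <- matrix(rnorm(81), 9, 9); z <- (z + t(z)) / 2; diag(z) <- 0
  g <- thresholdProportional(connectivityMatrix(z), 0.125)
  expect_identical(edgeCount(g), 4L)
})
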