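# From ROI time series to Fisher-z connectivity and density-thresholded
# binary networks.

#' Zero-phase Butterworth band-pass filter
#'
#' Removes each region's mean, then applies a zero-phase (forward-backward)
#' Butterworth band-pass per column. Typical bands for this kind of data
#' are 0.01-0.15 Hz (human, TR ~ 1.79 s) and 0.01-0.1 Hz (rat, TR ~ 1.7 s).
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param lowHz,highHz pass-band edges in Hz; \code{highHz} must stay below
#'   the Nyquist frequency 1/(2 TR).
#' @param filterOrder Butterworth order (default 2; the effective order is
#'   doubled by the forward-backward pass).
#' @return Filtered \linkS4class{RoiTimeSeries} of identical length.
#' @export
bandpass <- function(ts, lowHz = 0.01, highHz = 0.15, filterOrder = 2L) {
  stopifnot(is(ts, "RoiTimeSeries"))
  nyq <- 1 / (2 * ts@samplingInterval)
  if (!(lowHz > 0) || !(highHz > lowHz))
    stop("need 0 < lowHz < highHz")
  if (highHz >= nyq)
    stop(sprintf("highHz = %g Hz is not below the Nyquist frequency %g Hz (TR = %g s)",
                 highHz, nyq, ts@samplingInterval))
  x <- sweep(ts@values, 2L, colMeans(ts@values))
  bf <- signal::butter(filterOrder, c(lowHz, highHz) / nyq, type = "pass")
  y <- apply(x, 2L, function(col) signal::filtfilt(bf, col))
  if (nrow(ts@values) == 1L) y <- matrix(y, 1L)
  roiTimeSeries(y, regionLabels = ts@regionLabels,
                samplingInterval = ts@samplingInterval,
                subjectId = ts@subjectId, condition = ts@condition,
                group = ts@group)
}

#' Pairwise Pearson correlation, Fisher z-transformed
#'
#' Computes the Pearson correlation between every pair of regional time
#' series and transforms it with \code{atanh}. The diagonal is forced to
#' zero. Degenerate inputs (a constant region, or a perfectly correlated
#' off-diagonal pair, for which z would be infinite) raise errors naming
#' the offending regions.
#'
#' @param ts a \linkS4class{RoiTimeSeries} with at least 3 time points.
#' @return A \linkS4class{ConnectivityMatrix}.
#' @export
correlationMatrix <- function(ts) {
  stopifnot(is(ts, "RoiTimeSeries"))
  x <- ts@values
  if (nrow(x) < 3L) stop("need at least 3 time points for correlation")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance region(s): ",
         paste(ts@regionLabels[sds == 0], collapse = ", "))
  r <- cor(x)
  diag(r) <- 0
  if (any(abs(r) >= 1)) {
    bad <- which(abs(r) >= 1, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    stop("degenerate |r| = 1 between regions: ",
         paste(sprintf("%s~%s", ts@regionLabels[bad[, 1]],
                       ts@regionLabels[bad[, 2]]), collapse = ", "))
  }
  z <- atanh(r)
  z <- (z + t(z)) / 2  # enforce exact symmetry against FP noise
  diag(z) <- 0
  connectivityMatrix(z, regionLabels = ts@regionLabels,
                     subjectId = ts@subjectId, condition = ts@condition,
                     group = ts@group)
}

#' Proportional (density) thresholding to a binary network
#'
#' Retains exactly \code{k = round(density * N(N-1)/2)} upper-triangle
#' entries with the largest z (signed ranking by default, so only the
#' strongest positive correlations survive at sparse densities; set
#' \code{rankAbsolute} for |z| ranking). \code{round} follows R's
#' round-half-even convention so edge counts are bit-reproducible across
#' platforms. Ties that straddle the cutoff are broken deterministically
#' by lexicographic (row, column) order, with a warning.
#'
#' @param cm a \linkS4class{ConnectivityMatrix}.
#' @param density target edge density in (0, 1).
#' @param rankAbsolute rank edges by absolute z.
#' @return A \linkS4class{BinaryNetwork} with exactly k edges.
#' @export
thresholdProportional <- function(cm, density, rankAbsolute = FALSE) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  a <- .thresholdCore(cm@z, density, rankAbsolute)
  binaryNetwork(a, regionLabels = cm@regionLabels, density = density)
}

# core used by both the exported operation and the density sweep
.thresholdCore <- function(z, density, rankAbsolute = FALSE) {
  if (!(density > 0 && density < 1)) stop("'density' must be in (0, 1)")
  n <- nrow(z)
  npairs <- n * (n - 1) / 2
  k <- round(density * npairs)
  if (k < 1) stop(sprintf("density %g yields k = 0 edges on %d nodes", density, n))
  if (k > npairs) stop("requested more edges than node pairs")
  ut <- which(upper.tri(z))
  vals <- z[ut]
  score <- if (rankAbsolute) abs(vals) else vals
  # order by decreasing score, then by (row, col) = increasing linear index
  ord <- order(-score, ut)
  cutoffScore <- score[ord[k]]
  if (k < npairs && score[ord[k + 1L]] == cutoffScore)
    warning(sprintf("ties at the density cutoff (score = %g); broken by (row, column) order",
                    cutoffScore))
  a <- matrix(0L, n, n)
  keep <- ut[ord[seq_len(k)]]
  a[keep] <- 1L
  a + t(a)
}

#' Export a BinaryNetwork as an edge list
#'
#' @param g a \linkS4class{BinaryNetwork}.
#' @return data.frame with columns \code{from}, \code{to} (region labels).
#' @export
edgeList <- function(g) {
  stopifnot(is(g, "BinaryNetwork"))
  e <- .edgeIndices(g)
  data.frame(from = g@regionLabels[e[, 1]], to = g@regionLabels[e[, 2]],
             stringsAsFactors = FALSE)
}
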