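# Density sweep, AUC summarization, and group-level hypothesis tests.

#' Sweep one connectivity matrix across the density grid
#'
#' For each density: proportional thresholding, the requested graph
#' metrics, and (optionally) the motif census. Undefined metric values
#' (e.g. L or sigma on a fully fragmented graph) are recorded as \code{NA}
#' with the reason in the \code{note} column, never silently dropped.
#' Small-worldness nulls are seeded per density level (nullSpec seed +
#' level index), so a sweep is reproducible independent of call order.
#'
#' @param cm a \linkS4class{ConnectivityMatrix}.
#' @param cfg a \linkS4class{SweepConfig}.
#' @return list with \code{metrics} (long data.frame: subject_id,
#'   condition, group, density, metric, value, note) and \code{motifs}
#'   (long data.frame: subject_id, condition, group, density, motif_class,
#'   count, cyclic), the latter NULL when motifs are disabled.
#' @export
sweepMetrics <- function(cm, cfg = sweepConfig()) {
  stopifnot(is(cm, "ConnectivityMatrix"), is(cfg, "SweepConfig"))
  validObject(cfg)
  mets <- intersect(c("C", "L", "Eglob", "Eloc", "sigma"), cfg@metrics)
  nd <- length(cfg@densities)
  vals <- matrix(NA_real_, nd, length(mets), dimnames = list(NULL, mets))
  notes <- matrix("", nd, length(mets), dimnames = list(NULL, mets))
  counts <- if (cfg@motifs)
    matrix(NA_real_, nd, 10L,
           dimnames = list(NULL, c(.motifNames, "cyclic", "acyclic")))
  for (i in seq_len(nd)) {
    a <- .thresholdCore(cm@z, cfg@densities[i], cfg@rankAbsolute)
    if ("C" %in% mets || "sigma" %in% mets) cc <- .clusteringAdj(a)
    ps <- path_stats_cpp(a)
    if ("C" %in% mets) vals[i, "C"] <- cc
    if ("L" %in% mets) {
      vals[i, "L"] <- ps[1]
      if (is.na(ps[1])) notes[i, "L"] <- "no reachable pairs"
    }
    if ("Eglob" %in% mets) vals[i, "Eglob"] <- ps[3]
    if ("Eloc" %in% mets) vals[i, "Eloc"] <- local_efficiency_cpp(a)
    if ("sigma" %in% mets) {
      if (is.na(ps[1])) {
        notes[i, "sigma"] <- "L undefined, sigma unavailable"
      } else {
        nulls_i <- cfg@nullSpec
        ref <- .withSeed(cfg@nullSpec@seed + i, .nullStatsRaw(a, nulls_i))
        if (ref$Cbar == 0) {
          notes[i, "sigma"] <- "degenerate null ensemble: mean clustering is 0"
        } else {
          vals[i, "sigma"] <- (cc / ref$Cbar) / (ps[1] / ref$Lbar)
        }
      }
    }
    if (cfg@motifs) {
      cnt <- motif_census_cpp(a)
      cyc <- .motifNames %in% .cyclicClasses
      counts[i, ] <- c(cnt, sum(cnt[cyc]), sum(cnt[!cyc]))
    }
  }
  metricsDf <- data.frame(subject_id = cm@subjectId, condition = cm@condition,
                          group = cm@group,
                          density = rep(cfg@densities, each = length(mets)),
                          metric = rep(mets, nd),
                          value = as.vector(t(vals)),
                          note = as.vector(t(notes)),
                          stringsAsFactors = FALSE)
  motifsDf <- NULL
  if (cfg@motifs) {
    cls <- colnames(counts)
    motifsDf <- data.frame(subject_id = cm@subjectId, condition = cm@condition,
                           group = cm@group,
                           density = rep(cfg@densities, each = length(cls)),
                           motif_class = rep(cls, nd),
                           count = as.vector(t(counts)),
                           cyclic = rep(c(.motifNames %in% .cyclicClasses,
                                          TRUE, FALSE), nd),
                           stringsAsFactors = FALSE)
  }
  list(metrics = metricsDf, motifs = motifsDf)
}

#' Trapezoidal area under a metric-versus-density curve
#'
#' The grid is uniform by default so the trapezoid rule differs from a
#' Riemann sum only at the end points. A constant curve c over
#' [dmin, dmax] gives c * (dmax - dmin). Missing values abort with the
#' offending densities listed: the user should raise the density floor
#' rather than have fragmented levels silently imputed.
#'
#' @param values metric values, one per density.
#' @param densities the density grid (>= 2 points, strictly increasing).
#' @return scalar AUC.
#' @export
aucCurve <- function(values, densities) {
  if (length(values) != length(densities))
    stop("curve and density grid lengths differ")
  if (length(densities) < 2L) stop("need at least 2 grid points")
  if (anyNA(values))
    stop("missing values at densities: ",
         paste(densities[is.na(values)], collapse = ", "))
  sum(diff(densities) * (head(values, -1) + values[-1]) / 2)
}

#' Per-subject AUC summaries from sweep tables
#'
#' @param sweepTable long metric table (as from \code{sweepMetrics},
#'   rbound across sessions) with columns subject_id, condition, group,
#'   density, metric (or motif_class), value (or count).
#' @return data.frame: subject_id, condition, group, metric, auc.
#' @export
subjectAUC <- function(sweepTable) {
  valueCol <- if ("value" %in% names(sweepTable)) "value" else "count"
  metricCol <- if ("metric" %in% names(sweepTable)) "metric" else "motif_class"
  sp <- split(sweepTable,
              list(sweepTable$subject_id, sweepTable$condition,
                   sweepTable[[metricCol]]), drop = TRUE)
  out <- lapply(sp, function(df) {
    df <- df[order(df$density), ]
    data.frame(subject_id = df$subject_id[1], condition = df$condition[1],
               group = df$group[1], metric = df[[metricCol]][1],
               auc = aucCurve(df[[valueCol]], df$density),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$metric, res$subject_id, res$condition), ]
}

#' Group-level t-tests on AUC summaries
#'
#' Paired design: paired t-test on per-subject (drug - placebo) AUC
#' differences, df = n - 1. Two-group design: classical pooled-variance
#' independent t-test (Welch optional), df = n1 + n2 - 2. Two-sided
#' p-values. The \code{direction} column gives the sign of the drug
#' (second condition) minus placebo (first condition) contrast.
#'
#' @param aucs data.frame from \code{\link{subjectAUC}}.
#' @param design "paired" or "two_group".
#' @param conditions length-2 character: reference (placebo-like) and
#'   treatment (drug-like) condition labels, in that order.
#' @param welch use Welch's t instead of pooled variance (two_group only).
#' @return data.frame: metric, design, t, df, p_raw, direction, n.
#' @export
groupTest <- function(aucs, design = c("paired", "two_group"),
                      conditions = c("placebo", "drug"), welch = FALSE) {
  design <- match.arg(design)
  stopifnot(all(c("subject_id", "condition", "metric", "auc") %in% names(aucs)))
  missingCond <- setdiff(conditions, unique(aucs$condition))
  if (length(missingCond))
    stop("condition(s) absent from AUC table: ",
         paste(missingCond, collapse = ", "))
  out <- lapply(split(aucs, aucs$metric), function(df) {
    a <- df[df$condition == conditions[1], ]
    b <- df[df$condition == conditions[2], ]
    if (design == "paired") {
      ids <- union(a$subject_id, b$subject_id)
      bad <- ids[!(ids %in% a$subject_id & ids %in% b$subject_id)]
      if (length(bad))
        stop("unpairable subject(s): ", paste(bad, collapse = ", "))
      diffs <- b$auc[match(ids, b$subject_id)] - a$auc[match(ids, a$subject_id)]
      if (length(diffs) < 2) stop("paired test needs at least 2 subjects")
      n <- length(diffs)
      md <- mean(diffs)
      if (sd(diffs) == 0) {
        if (any(diffs != 0))
          stop("zero-variance nonzero differences for metric '", df$metric[1],
               "': t is undefined (degenerate input)")
        # all differences exactly zero: no evidence of any effect
        tt <- list(statistic = c(t = 0), parameter = c(df = n - 1),
                   p.value = 1)
      } else {
        tt <- t.test(diffs)
      }
    } else {
      if (nrow(a) < 2 || nrow(b) < 2)
        stop("two-group test needs at least 2 subjects per group")
      tt <- t.test(b$auc, a$auc, var.equal = !welch)
      n <- nrow(a) + nrow(b)
      md <- mean(b$auc) - mean(a$auc)
    }
    data.frame(metric = df$metric[1], design = design,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               direction = if (md > 0) "increase" else if (md < 0) "decrease" else "none",
               mean_diff = md, n = n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg FDR adjustment for one test family
#'
#' Step-up BH with monotonicity enforcement (via \code{stats::p.adjust}).
#' Graph metrics (5 values) and motif classes (8 values) are adjusted as
#' separate families by the pipeline.
#'
#' @param p numeric p-values in [0, 1].
#' @param family label used in error messages.
#' @return adjusted p-values, same order.
#' @export
fdrAdjust <- function(p, family = "tests") {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values outside [0, 1] in family '", family, "'")
  p.adjust(p, method = "BH")
}

#' Run the full group analysis on a set of sessions
#'
#' Optional band-pass filtering, Fisher-z connectivity, density sweep,
#' per-subject AUC, and group t-tests with FDR applied within families:
#' the five graph metrics as one family, the eight motif classes as
#' another, and the cyclic/acyclic totals as a third.
#'
#' @param sessions list of \linkS4class{RoiTimeSeries}.
#' @param design "paired" or "two_group".
#' @param sweep a \linkS4class{SweepConfig}.
#' @param bandpassSpec NULL to skip filtering, or a list with elements
#'   \code{lowHz}, \code{highHz} and optionally \code{filterOrder}.
#' @param conditions reference and treatment labels.
#' @param welch use Welch's t for two-group designs.
#' @return list with \code{curves}, \code{motifCurves}, \code{auc},
#'   \code{motifAuc}, and \code{tests} (with p_fdr per family).
#' @export
analyzeStudy <- function(sessions, design = c("paired", "two_group"),
                         sweep = sweepConfig(), bandpassSpec = NULL,
                         conditions = c("placebo", "drug"), welch = FALSE) {
  design <- match.arg(design)
  swept <- lapply(sessions, function(ts) {
    if (!is.null(bandpassSpec))
      ts <- bandpass(ts, lowHz = bandpassSpec$lowHz,
                     highHz = bandpassSpec$highHz,
                     filterOrder = if (is.null(bandpassSpec$filterOrder)) 2L
                                   else bandpassSpec$filterOrder)
    sweepMetrics(correlationMatrix(ts), sweep)
  })
  curves <- do.call(rbind, lapply(swept, `[[`, "metrics"))
  motifCurves <- if (sweep@motifs)
    do.call(rbind, lapply(swept, `[[`, "motifs")) else NULL
  auc <- subjectAUC(curves)
  tests <- groupTest(auc, design, conditions, welch)
  tests$family <- "graph_metrics"
  motifAuc <- NULL
  if (!is.null(motifCurves)) {
    motifAuc <- subjectAUC(motifCurves)
    classes <- .motifNames
    mtRaw <- groupTest(motifAuc[motifAuc$metric %in% classes, ],
                       design, conditions, welch)
    mtRaw$family <- "motifs"
    mtTot <- groupTest(motifAuc[motifAuc$metric %in% c("cyclic", "acyclic"), ],
                       design, conditions, welch)
    mtTot$family <- "motif_totals"
    tests <- rbind(tests, mtRaw, mtTot)
  }
  tests$p_fdr <- NA_real_
  for (fam in unique(tests$family)) {
    idx <- tests$family == fam
    tests$p_fdr[idx] <- fdrAdjust(tests$p_raw[idx], family = fam)
  }
  list(curves = curves, motifCurves = motifCurves, auc = auc,
       motifAuc = motifAuc, tests = tests)
}
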