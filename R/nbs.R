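# Network Based Statistics: edgewise t statistics, supra-threshold
# connected components, and permutation FWER control on the maximal
# component size.

# Collect a list of ConnectivityMatrix objects into upper-triangle rows.
# Returns the per-session value matrix (sessions x edges), edge indices,
# labels, and session metadata.
.stackMatrices <- function(matrices) {
  stopifnot(length(matrices) >= 2)
  labs <- regionLabels(matrices[[1]])
  for (m in matrices)
    if (!identical(regionLabels(m), labs))
      stop("region labels differ across matrices; labels are the join key")
  n <- length(labs)
  ut <- which(upper.tri(matrix(0, n, n)))
  x <- t(vapply(matrices, function(m) zMatrix(m)[ut], numeric(length(ut))))
  list(x = x, ut = ut, n = n, labels = labs,
       subject = vapply(matrices, function(m) m@subjectId, ""),
       condition = vapply(matrices, function(m) m@condition, ""))
}

# Paired per-subject difference rows (drug - placebo), subjects x edges.
.pairedDiffs <- function(stack, conditions) {
  ia <- stack$condition == conditions[1]
  ib <- stack$condition == conditions[2]
  ids <- union(stack$subject[ia], stack$subject[ib])
  bad <- ids[!(ids %in% stack$subject[ia] & ids %in% stack$subject[ib])]
  if (length(bad)) stop("unpairable subject(s): ", paste(bad, collapse = ", "))
  a <- stack$x[ia, , drop = FALSE][match(ids, stack$subject[ia]), , drop = FALSE]
  b <- stack$x[ib, , drop = FALSE][match(ids, stack$subject[ib]), , drop = FALSE]
  b - a
}

.tFromDiffs <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  v <- (colSums(d * d) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t <- ifelse(v == 0, 0, m / sqrt(v / n))
  list(t = t, df = n - 1)
}

.tTwoGroup <- function(xa, xb) {
  n1 <- nrow(xa); n2 <- nrow(xb)
  m1 <- colMeans(xa); m2 <- colMeans(xb)
  v1 <- (colSums(xa * xa) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(xb * xb) - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * pmax(v1, 0) + (n2 - 1) * pmax(v2, 0)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se == 0, 0, (m2 - m1) / se)
  list(t = t, df = n1 + n2 - 2)
}

#' Edgewise t-statistic matrix
#'
#' Per upper-triangle edge, a paired t on the per-subject Fisher-z
#' differences (treatment minus reference) or a pooled-variance two-sample
#' t across groups. Edges with zero variance get t = 0 (never
#' supra-threshold) rather than NaN, with a warning.
#'
#' @param matrices list of \linkS4class{ConnectivityMatrix} with subject
#'   and condition metadata set.
#' @param design "paired" or "two_group".
#' @param conditions reference and treatment condition labels.
#' @return symmetric t matrix with zero diagonal, attribute \code{df}.
#' @export
edgewiseT <- function(matrices, design = c("paired", "two_group"),
                      conditions = c("placebo", "drug")) {
  design <- match.arg(design)
  stack <- .stackMatrices(matrices)
  if (design == "paired") {
    d <- .pairedDiffs(stack, conditions)
    res <- .tFromDiffs(d)
    zv <- apply(d, 2, function(col) all(col == col[1]) && col[1] != 0)
  } else {
    xa <- stack$x[stack$condition == conditions[1], , drop = FALSE]
    xb <- stack$x[stack$condition == conditions[2], , drop = FALSE]
    if (nrow(xa) < 2 || nrow(xb) < 2)
      stop("two-group design needs >= 2 sessions per condition")
    res <- .tTwoGroup(xa, xb)
    zv <- logical(length(res$t))
  }
  if (any(res$t == 0 & zv))
    warning("zero-variance nonzero difference at some edges; t set to 0 there")
  tm <- matrix(0, stack$n, stack$n, dimnames = list(stack$labels, stack$labels))
  tm[stack$ut] <- res$t
  tm <- tm + t(tm)
  attr(tm, "df") <- res$df
  tm
}

# Union-find over an edge subset; returns component id per edge.
.edgeComponents <- function(ei, ej) {
  nodes <- sort(unique(c(ei, ej)))
  parent <- seq_along(nodes)
  idx <- function(v) match(v, nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  a <- idx(ei); b <- idx(ej)
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(a, find, 0L)
  match(roots, unique(roots))
}

#' Connected components of supra-threshold edges
#'
#' Builds the graph of edges whose t exceeds the primary threshold
#' (\code{t > threshold} for tail "greater", \code{t < -threshold} for
#' "less") and returns its connected components, sized by extent (edge
#' count), sorted by decreasing size.
#'
#' @param tMatrix symmetric edgewise t matrix.
#' @param threshold primary threshold (> 0).
#' @param tail "greater" or "less".
#' @return list of components: \code{edges} (2-column index matrix),
#'   \code{nodes} (indices), \code{size} (edge count), \code{minT} (the
#'   smallest supra-threshold |t| in the component).
#' @export
supraThresholdComponents <- function(tMatrix, threshold, tail = "greater") {
  stopifnot(threshold > 0)
  sel <- if (tail == "greater") tMatrix > threshold else tMatrix < -threshold
  sel[lower.tri(sel, diag = TRUE)] <- FALSE
  e <- which(sel, arr.ind = TRUE)
  if (nrow(e) == 0) return(list())
  comp <- .edgeComponents(e[, 1], e[, 2])
  out <- lapply(split(seq_len(nrow(e)), comp), function(rows) {
    ed <- e[rows, , drop = FALSE]
    tv <- tMatrix[ed]
    list(edges = ed, nodes = sort(unique(c(ed))), size = nrow(ed),
         intensity = sum(abs(tv) - threshold), minT = min(abs(tv)))
  })
  out[order(-vapply(out, `[[`, 0, "size"))]
}

# Max component statistic (extent or intensity) of one permutation's t row.
.maxComponentStat <- function(tvec, ut, n, threshold, tail, sizeType) {
  sel <- if (tail == "greater") tvec > threshold else tvec < -threshold
  if (!any(sel)) return(0)
  lin <- ut[sel]
  ei <- ((lin - 1L) %% n) + 1L
  ej <- ((lin - 1L) %/% n) + 1L
  comp <- .edgeComponents(ei, ej)
  if (sizeType == "extent") {
    max(tabulate(comp))
  } else {
    exc <- abs(tvec[sel]) - threshold
    max(vapply(split(exc, comp), sum, 0))
  }
}

# One-tailed NBS pass; returns components with p_fwer plus the null maxima.
.nbsOneTail <- function(stack, cfg, tail, conditions) {
  n <- stack$n
  thr <- cfg@primaryThresholdT
  if (cfg@design == "paired") {
    d <- .pairedDiffs(stack, conditions)
    ns <- nrow(d)
    obs <- .tFromDiffs(d)$t
    exhaustive <- 2^ns <= cfg@nPermutations
    signs <- if (exhaustive) {
      message(sprintf("NBS: 2^%d = %d sign patterns <= %d permutations; using full enumeration",
                      ns, 2^ns, cfg@nPermutations))
      as.matrix(expand.grid(rep(list(c(-1, 1)), ns)))
    } else {
      .withSeed(cfg@seed, matrix(sample(c(-1, 1), cfg@nPermutations * ns,
                                        replace = TRUE),
                                 ncol = ns))
    }
    ssFixed <- colSums(d * d)
    nullMax <- numeric(nrow(signs))
    chunk <- 512L
    for (s0 in seq(1L, nrow(signs), by = chunk)) {
      rows <- s0:min(s0 + chunk - 1L, nrow(signs))
      mm <- (signs[rows, , drop = FALSE] %*% d) / ns
      for (r in seq_along(rows)) {
        v <- (ssFixed - ns * mm[r, ]^2) / (ns - 1)
        tv <- ifelse(v <= 0, 0, mm[r, ] / sqrt(v / ns))
        nullMax[rows[r]] <- .maxComponentStat(tv, stack$ut, n, thr, tail,
                                              cfg@componentSize)
      }
    }
  } else {
    ia <- which(stack$condition == conditions[1])
    ib <- which(stack$condition == conditions[2])
    ns <- length(ia) + length(ib)
    obs <- .tTwoGroup(stack$x[ia, , drop = FALSE],
                      stack$x[ib, , drop = FALSE])$t
    exhaustive <- FALSE
    perms <- .withSeed(cfg@seed,
      replicate(cfg@nPermutations, sample(ns, length(ia)), simplify = FALSE))
    nullMax <- vapply(perms, function(pa) {
      tv <- .tTwoGroup(stack$x[pa, , drop = FALSE],
                       stack$x[-pa, , drop = FALSE])$t
      .maxComponentStat(tv, stack$ut, n, thr, tail, cfg@componentSize)
    }, 0)
  }
  tm <- matrix(0, n, n, dimnames = list(stack$labels, stack$labels))
  tm[stack$ut] <- obs
  tm <- tm + t(tm)
  comps <- supraThresholdComponents(tm, thr, tail)
  for (i in seq_along(comps)) {
    statObs <- if (cfg@componentSize == "extent") comps[[i]]$size
               else comps[[i]]$intensity
    p <- if (exhaustive) mean(nullMax >= statObs)
         else (1 + sum(nullMax >= statObs)) / (1 + length(nullMax))
    comps[[i]]$pFwer <- p
  }
  list(tMatrix = tm, components = comps, nullMax = nullMax,
       nSubjects = ns, exhaustive = exhaustive)
}

#' Network Based Statistics test
#'
#' Tests, at the level of connected components of supra-threshold edges,
#' whether any component is larger than expected under the permutation
#' null of the maximal component size. Paired designs permute by
#' independent per-subject sign flips of the difference matrices (full
#' enumeration when 2^n does not exceed the permutation budget, logged);
#' two-group designs shuffle group labels. FWER p-values use the add-one
#' convention, so p is never 0. A two-sided test runs both one-sided
#' passes and Bonferroni-corrects across the two tails.
#'
#' @param matrices list of \linkS4class{ConnectivityMatrix}.
#' @param cfg a \linkS4class{NBSConfig}.
#' @param conditions reference and treatment condition labels.
#' @return An \linkS4class{NBSResult}.
#' @export
nbsTest <- function(matrices, cfg, conditions = c("placebo", "drug")) {
  stopifnot(is(cfg, "NBSConfig"))
  validObject(cfg)
  stack <- .stackMatrices(matrices)
  nPaired <- sum(stack$condition == conditions[1])
  if (cfg@design == "paired" && 2^nPaired < 20)
    warning(sprintf("only %d sign patterns available; minimum achievable p is %.3g",
                    2^nPaired, 1 / 2^nPaired))
  tails <- if (cfg@tail == "two_sided") c("greater", "less") else cfg@tail
  passes <- lapply(tails, function(tl) .nbsOneTail(stack, cfg, tl, conditions))
  comps <- list()
  for (i in seq_along(passes)) {
    for (comp in passes[[i]]$components) {
      if (length(tails) == 2) comp$pFwer <- min(1, 2 * comp$pFwer)
      comp$tail <- tails[i]
      comp$edges <- cbind(
        data.frame(from = stack$labels[comp$edges[, 1]],
                   to = stack$labels[comp$edges[, 2]],
                   stringsAsFactors = FALSE),
        t = passes[[i]]$tMatrix[comp$edges])
      comp$nodes <- stack$labels[comp$nodes]
      comps[[length(comps) + 1]] <- comp
    }
  }
  comps <- comps[order(-vapply(comps, `[[`, 0, "size"))]
  tm <- passes[[1]]$tMatrix
  res <- new("NBSResult", components = comps, tMatrix = tm,
             perNodeCounts = numeric(0), nullMaxSize = passes[[1]]$nullMax,
             config = list(primary_threshold_t = cfg@primaryThresholdT,
                           n_permutations = cfg@nPermutations,
                           alpha = cfg@alpha, tail = cfg@tail,
                           design = cfg@design,
                           component_size = cfg@componentSize,
                           seed = cfg@seed,
                           exhaustive = passes[[1]]$exhaustive,
                           n_subjects = passes[[1]]$nSubjects))
  res@perNodeCounts <- alteredConnectionCounts(res)
  res
}

#' Altered-connection counts per node
#'
#' Node degree restricted to the edges of significant components
#' (p_fwer <= alpha), i.e. the number of altered connections per node.
#' Counts sum to twice the significant edge count (handshake). An empty
#' report (no significant component) is returned as a zero-length vector,
#' not an error.
#'
#' @param result an \linkS4class{NBSResult}.
#' @param alpha significance level (defaults to the one in the result's
#'   config).
#' @return named numeric vector, sorted by decreasing count.
#' @export
alteredConnectionCounts <- function(result, alpha = NULL) {
  stopifnot(is(result, "NBSResult"))
  if (is.null(alpha)) alpha <- result@config$alpha
  sig <- Filter(function(comp) comp$pFwer <= alpha, result@components)
  if (!length(sig)) return(setNames(numeric(0), character(0)))
  ends <- unlist(lapply(sig, function(comp) c(comp$edges$from, comp$edges$to)))
  cnt <- sort(table(ends), decreasing = TRUE)
  out <- as.numeric(cnt)
  names(out) <- names(cnt)
  out
}
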