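# Delimited-text I/O: sessions, matrices, manifests, config echoes.
# TSV with '.' decimal is the interchange dialect; region labels are the
# join key everywhere, never positional indices across files.

#' Read / write ROI time series as TSV
#'
#' First row = region labels, subsequent rows = time points.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param path file path.
#' @export
writeRoiTimeSeries <- function(ts, path) {
  stopifnot(is(ts, "RoiTimeSeries"))
  write.table(ts@values, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeRoiTimeSeries
#' @param samplingInterval,subjectId,condition,group metadata not stored in
#'   the TSV itself (the manifest carries them).
#' @export
readRoiTimeSeries <- function(path, samplingInterval = 1,
                              subjectId = NA_character_,
                              condition = NA_character_,
                              group = NA_character_) {
  x <- as.matrix(read.delim(path, check.names = FALSE))
  roiTimeSeries(x, samplingInterval = samplingInterval,
                subjectId = subjectId, condition = condition, group = group)
}

#' Read / write a ConnectivityMatrix as labelled TSV
#'
#' @param cm a \linkS4class{ConnectivityMatrix}.
#' @param path file path.
#' @export
writeConnectivityMatrix <- function(cm, path) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  df <- data.frame(region = cm@regionLabels, cm@z, check.names = FALSE)
  colnames(df) <- c("region", cm@regionLabels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConnectivityMatrix
#' @param subjectId,condition,group provenance to attach.
#' @export
readConnectivityMatrix <- function(path, subjectId = NA_character_,
                                   condition = NA_character_,
                                   group = NA_character_) {
  df <- read.delim(path, check.names = FALSE)
  labs <- as.character(df$region)
  z <- as.matrix(df[, -1, drop = FALSE])
  connectivityMatrix(z, regionLabels = labs, subjectId = subjectId,
                     condition = condition, group = group)
}

#' Write a simulated study to a directory
#'
#' Emits one TSV per session, a manifest table (subject id, condition,
#' group, seed, file path) and the generating configuration echoed as
#' YAML.
#'
#' @param study result of \code{\link{simulateStudy}}.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- study$manifest
  man$file <- sprintf("session_%03d_%s_%s.tsv", seq_len(nrow(man)),
                      man$subject_id, man$condition)
  for (i in seq_len(nrow(man)))
    writeRoiTimeSeries(study$sessions[[i]], file.path(dir, man$file[i]))
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  yaml::write_yaml(study$config, file.path(dir, "config.yaml"))
  invisible(man)
}

#' Read a study directory written by \code{\link{writeStudy}}
#'
#' @param dir study directory containing \code{manifest.tsv} and session
#'   TSVs.
#' @return list with \code{sessions}, \code{manifest}, \code{config}.
#' @export
readStudy <- function(dir) {
  manPath <- file.path(dir, "manifest.tsv")
  if (!file.exists(manPath)) stop("no manifest.tsv in ", dir)
  man <- read.delim(manPath, colClasses = c(subject_id = "character"))
  cfgPath <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfgPath)) yaml::read_yaml(cfgPath) else NULL
  tr <- if (!is.null(cfg$sampling_interval)) cfg$sampling_interval else 1
  sessions <- lapply(seq_len(nrow(man)), function(i) {
    f <- file.path(dir, man$file[i])
    if (!file.exists(f)) stop("missing session file: ", f)
    readRoiTimeSeries(f, samplingInterval = tr,
                      subjectId = man$subject_id[i],
                      condition = man$condition[i], group = man$group[i])
  })
  list(sessions = sessions, manifest = man, config = cfg)
}
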