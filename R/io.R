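# Delimited-text readers and writers.  All artifacts carry a provenance
# header comment (package version, seed, config checksum); readers skip
# '#'-prefixed lines.  Values are written at 17 significant digits so that
# write-then-read round-trips are exact at double precision.

.provenanceLine <- function(seed = NA, configHash = NA) {
  paste0("# fbnfuse ", as.character(utils::packageVersion("fbnfuse")),
         " | seed=", seed, " | config=", configHash)
}

# Cheap deterministic checksum of a flat key=value configuration text.
.configHash <- function(txt) {
  s <- utf8ToInt(paste(txt, collapse = "\n"))
  sprintf("%08x", sum(s * (seq_along(s) %% 997)) %% 2147483647)
}

.detectDelim <- function(line) if (grepl("\t", line, fixed = TRUE)) "\t" else ","

.readDelimLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("file ", path, " has no data rows", call. = FALSE)
  delim <- .detectDelim(lines[1])
  list(fields = strsplit(lines, delim, fixed = TRUE), delim = delim)
}

#' Read an ROI time-series file
#'
#' Reads one subject's delimited time-series file: a header row of ROI
#' labels followed by one row per timepoint (comma or tab, auto-detected;
#' `#` comment lines are skipped). Ragged rows, non-numeric cells and
#' constant ROI columns are rejected with errors naming the offending
#' row/column.
#'
#' @param path file path.
#' @param subjectID subject identifier; defaults to the file name without
#'   extension.
#' @return An [ROITimeSeries-class].
#' @seealso [writeTimeSeries()]
#' @export
readTimeSeries <- function(path, subjectID = NULL) {
  parsed <- .readDelimLines(path)
  fields <- parsed$fields
  header <- trimws(fields[[1]])
  n <- length(header)
  rows <- fields[-1]
  X <- matrix(NA_real_, length(rows), n)
  for (r in seq_along(rows)) {
    f <- trimws(rows[[r]])
    if (length(f) != n)
      stop("ragged row ", r, " in ", path, ": ", length(f),
           " fields, expected ", n, call. = FALSE)
    vals <- suppressWarnings(as.numeric(f))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      stop("non-numeric cell at row ", r, ", column ", bad, " ('",
           f[bad], "') in ", path, call. = FALSE)
    }
    X[r, ] <- vals
  }
  colnames(X) <- header
  if (is.null(subjectID))
    subjectID <- sub("\\.[^.]*$", "", basename(path))
  tryCatch(ROITimeSeries(X, subjectID = subjectID),
           error = function(e)
             stop("invalid time series in ", path, ": ",
                  conditionMessage(e), call. = FALSE))
}

#' Write an ROI time-series file
#'
#' @param ts an [ROITimeSeries-class].
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @param seed,configHash provenance recorded in the header comment.
#' @return `path`, invisibly.
#' @export
writeTimeSeries <- function(ts, path, delim = "\t", seed = NA,
                            configHash = NA) {
  stopifnot(is(ts, "ROITimeSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceLine(seed, configHash), con)
  writeLines(paste(roiLabels(ts), collapse = delim), con)
  apply(ts@data, 1, function(row)
    writeLines(paste(sprintf("%.17g", row), collapse = delim), con))
  invisible(path)
}

#' Read a connectivity matrix file
#'
#' Square delimited matrix with a label header row and a label first
#' column, as written by [writeConnectivityMatrix()].
#'
#' @param path file path.
#' @param method method label to record (default `"FUSED"`).
#' @param sparsityParam provenance to record.
#' @return A [ConnectivityMatrix-class].
#' @export
readConnectivityMatrix <- function(path, method = "FUSED",
                                   sparsityParam = NA_real_) {
  parsed <- .readDelimLines(path)
  fields <- parsed$fields
  labs <- trimws(fields[[1]])[-1]
  n <- length(labs)
  W <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  rows <- fields[-1]
  if (length(rows) != n)
    stop("expected ", n, " matrix rows in ", path, ", found ",
         length(rows), call. = FALSE)
  for (r in seq_len(n)) {
    f <- trimws(rows[[r]])
    if (length(f) != n + 1L)
      stop("ragged row ", r, " in ", path, call. = FALSE)
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(vals))
      stop("non-numeric cell at row ", r, " in ", path, call. = FALSE)
    W[r, ] <- vals
  }
  ConnectivityMatrix(W, method = method, sparsityParam = sparsityParam)
}

#' Write a connectivity matrix file
#'
#' @param W a [ConnectivityMatrix-class].
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @param seed,configHash provenance recorded in the header comment.
#' @return `path`, invisibly.
#' @export
writeConnectivityMatrix <- function(W, path, delim = "\t", seed = NA,
                                    configHash = NA) {
  stopifnot(is(W, "ConnectivityMatrix"))
  labs <- roiLabels(W)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceLine(seed, configHash), con)
  writeLines(paste(c("ROI", labs), collapse = delim), con)
  M <- W@weights
  for (r in seq_along(labs))
    writeLines(paste(c(labs[r], sprintf("%.17g", M[r, ])),
                     collapse = delim), con)
  invisible(path)
}

#' Read a cohort manifest
#'
#' Delimited file with header `subject_id,label,timeseries_path`. Labels
#' are case-insensitive `ASD` (patient) / `NC` (control); relative paths
#' are resolved against the manifest's directory. Duplicate subject ids,
#' unknown labels and missing files are rejected.
#'
#' @param path manifest path.
#' @return data.frame with columns `subjectID`, `label` (factor NC/ASD) and
#'   `path` (resolved).
#' @export
readManifest <- function(path) {
  parsed <- .readDelimLines(path)
  fields <- parsed$fields
  header <- tolower(trimws(fields[[1]]))
  need <- c("subject_id", "label", "timeseries_path")
  if (!all(need %in% header))
    stop("manifest ", path, " must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  idx <- match(need, header)
  rows <- fields[-1]
  df <- data.frame(
    subjectID = vapply(rows, function(f) trimws(f[idx[1]]), character(1)),
    labelRaw = vapply(rows, function(f) trimws(f[idx[2]]), character(1)),
    pathRaw = vapply(rows, function(f) trimws(f[idx[3]]), character(1)),
    stringsAsFactors = FALSE)
  dup <- df$subjectID[duplicated(df$subjectID)]
  if (length(dup))
    stop("duplicate subject_id in manifest: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  labels <- .normalizeLabels(df$labelRaw)
  base <- dirname(normalizePath(path))
  resolved <- ifelse(grepl("^(/|[A-Za-z]:)", df$pathRaw), df$pathRaw,
                     file.path(base, df$pathRaw))
  missing <- !file.exists(resolved)
  if (any(missing))
    stop("time-series file(s) not found: ",
         paste(resolved[missing], collapse = ", "), call. = FALSE)
  data.frame(subjectID = df$subjectID, label = labels, path = resolved,
             stringsAsFactors = FALSE)
}

#' Write a cohort to disk
#'
#' Writes one time-series file per subject plus a `manifest.csv`, in the
#' exact formats consumed by [readManifest()] / [readTimeSeries()] and the
#' command-line interface.
#'
#' @param cohort list with `timeSeries` and `labels`, as returned by
#'   [simulateBoldCohort()].
#' @param dir output directory (created if needed).
#' @param seed provenance recorded in headers.
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(cohort$timeSeries, subjectID, character(1))
  files <- paste0(ids, ".tsv")
  for (s in seq_along(ids))
    writeTimeSeries(cohort$timeSeries[[s]], file.path(dir, files[s]),
                    seed = seed)
  manifest <- file.path(dir, "manifest.csv")
  con <- file(manifest, "w")
  writeLines(c(.provenanceLine(seed),
               "subject_id,label,timeseries_path",
               paste(ids, as.character(cohort$labels), files, sep = ",")),
             con)
  close(con)
  invisible(manifest)
}

#' Load all time series referenced by a manifest
#'
#' @param manifest data.frame from [readManifest()] or a manifest path.
#' @return List with `timeSeries` (list of [ROITimeSeries-class]) and
#'   `labels` (factor NC/ASD).
#' @export
loadCohort <- function(manifest) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  tsList <- lapply(seq_len(nrow(manifest)), function(i)
    readTimeSeries(manifest$path[i], subjectID = manifest$subjectID[i]))
  list(timeSeries = tsList, labels = manifest$label)
}
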