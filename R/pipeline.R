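# End-to-end orchestration: manifest -> estimate -> threshold -> stack ->
# fuse -> classify, with on-disk artifacts.

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run: the estimator list and
#' their parameter grids, the fusion settings, the t-test threshold and the
#' master seed. Serializes losslessly to flat `key = value` text via
#' [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param estimators character subset of `c("PC","SR","MI","CC")`.
#' @param grids named list of per-estimator grids (see [defaultGrids()]).
#' @param pThreshold t-test selection threshold (the protocol's canonical
#'   thresholds are 0.01, 0.05, 0.001 and 0.005; 0.001 is the default).
#' @param alpha,rank,epsilon,tMax,reconMode,reorthonormalize fusion
#'   parameters, see [FusionConfig()]. The regularization is scale-coupled
#'   to the slice energy: the optimum of 10 reported for raw 116-ROI
#'   networks (slice energy of order 10^3) corresponds to about 0.01 once
#'   slices are rescaled to unit Frobenius norm, which is the pipeline
#'   default here since `normalizeSlices` defaults to on.
#' @param normalizeSlices rescale slices to unit Frobenius norm.
#' @param seed master seed (fusion core initialization and any
#'   permutation).
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(estimators = c("PC", "SR", "MI", "CC"),
                           grids = defaultGrids(), pThreshold = 0.001,
                           alpha = 0.01, rank = 50L, epsilon = 1e-5,
                           tMax = 100L, reconMode = "pearson",
                           reorthonormalize = FALSE,
                           normalizeSlices = TRUE, seed = 1L) {
  stopifnot(all(lengths(grids[estimators]) >= 1L))
  structure(list(estimators = estimators, grids = grids,
                 pThreshold = as.numeric(pThreshold),
                 alpha = as.numeric(alpha), rank = as.integer(rank),
                 epsilon = as.numeric(epsilon), tMax = as.integer(tMax),
                 reconMode = reconMode,
                 reorthonormalize = isTRUE(reorthonormalize),
                 normalizeSlices = isTRUE(normalizeSlices),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

.configText <- function(config) {
  c(paste0("estimators = ", paste(config$estimators, collapse = ",")),
    vapply(config$estimators, function(e)
      paste0("grid.", e, " = ",
             paste(sprintf("%.17g", config$grids[[e]]), collapse = ",")),
      character(1)),
    paste0("p_threshold = ", sprintf("%.17g", config$pThreshold)),
    paste0("alpha = ", sprintf("%.17g", config$alpha)),
    paste0("rank = ", config$rank),
    paste0("epsilon = ", sprintf("%.17g", config$epsilon)),
    paste0("t_max = ", config$tMax),
    paste0("recon_mode = ", config$reconMode),
    paste0("reorthonormalize = ", tolower(config$reorthonormalize)),
    paste0("normalize_slices = ", tolower(config$normalizeSlices)),
    paste0("seed = ", config$seed))
}

#' Write a pipeline configuration as flat key = value text
#'
#' @param config a [pipelineConfig()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  writeLines(c("# fbnfuse pipeline configuration", .configText(config)),
             path)
  invisible(path)
}

#' Read a pipeline configuration from flat key = value text
#'
#' @param path configuration path.
#' @return A [pipelineConfig()] object.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x)
    paste(x[-1], collapse = "="), character(1)))
  get <- function(k) vals[match(k, keys)]
  estimators <- strsplit(get("estimators"), ",")[[1]]
  grids <- lapply(estimators, function(e)
    as.numeric(strsplit(get(paste0("grid.", e)), ",")[[1]]))
  names(grids) <- estimators
  pipelineConfig(
    estimators = estimators, grids = grids,
    pThreshold = as.numeric(get("p_threshold")),
    alpha = as.numeric(get("alpha")), rank = as.integer(get("rank")),
    epsilon = as.numeric(get("epsilon")), tMax = as.integer(get("t_max")),
    reconMode = get("recon_mode"),
    reorthonormalize = identical(get("reorthonormalize"), "true"),
    normalizeSlices = identical(get("normalize_slices"), "true"),
    seed = as.integer(get("seed")))
}

.fusionFromConfig <- function(config) {
  FusionConfig(alpha = config$alpha, rank = config$rank,
               tMax = config$tMax, epsilon = config$epsilon,
               seed = config$seed, reconMode = config$reconMode,
               reorthonormalize = config$reorthonormalize)
}

# most frequent value of a vector, earliest occurrence on ties
.modalValue <- function(x) {
  tab <- table(factor(x, levels = unique(x)))
  as.numeric(names(tab)[which.max(tab)])
}

#' Interclass-distance diagnostic: joint-embedding vs averaging fusion
#'
#' Builds, for every subject, both the joint-embedding fused network and
#' the naive entrywise-average of the same single-view networks, and
#' returns the interclass distance ([interclassDistance()]) of each. The
#' diagnostic quantifies how much class separability each fusion scheme
#' preserves; averaging signed edge weights cancels oppositely signed
#' connections and typically shrinks the distance.
#'
#' @param tsList list of [ROITimeSeries-class] objects.
#' @param labels class labels aligned with `tsList`.
#' @param removeProps named removal proportions for the dense views (see
#'   [fuseSubject()]); typically the modal parameters selected by the
#'   classification protocol.
#' @param srLambda sparse-representation penalty.
#' @param config a [FusionConfig-class].
#' @param normalizeSlices rescale slices before stacking.
#' @param estimators views to fuse, in slice order.
#' @return Named numeric vector with elements `fused` and `averaging`.
#' @export
fusionDistanceDiagnostic <- function(tsList, labels,
                                     removeProps = c(PC = 0, MI = 0,
                                                     CC = 0),
                                     srLambda = 2^-5,
                                     config = FusionConfig(),
                                     normalizeSlices = TRUE,
                                     estimators = c("PC", "SR", "MI",
                                                    "CC")) {
  fused <- vector("list", length(tsList))
  avg <- vector("list", length(tsList))
  for (s in seq_along(tsList)) {
    fb <- fuseSubject(tsList[[s]], removeProps = removeProps,
                      srLambda = srLambda, config = config,
                      normalizeSlices = normalizeSlices,
                      estimators = estimators)
    fused[[s]] <- fb$fused
    avg[[s]] <- averagingFusion(fb$views)
  }
  c(fused = interclassDistance(fused, labels),
    averaging = interclassDistance(avg, labels))
}

#' Run the full fusion-and-classification pipeline
#'
#' Loads a cohort from a manifest, runs the nested LOOCV protocol
#' ([loocvEvaluate()]), and writes the artifacts: one fused network per
#' subject (built at the modal per-estimator parameters selected across
#' folds), the per-fold log, the metrics report and the configuration.
#' Fully deterministic given the configuration seed.
#'
#' @param manifest manifest path or data.frame from [readManifest()].
#' @param config a [pipelineConfig()].
#' @param outputDir directory for artifacts; `NULL` skips writing.
#' @param includeSingleViews also evaluate the single-view baselines.
#' @param verbose emit progress messages.
#' @return List with `fused` ([MetricsReport-class]), optionally
#'   `singleViews`, `modalParams` (named numeric), and `files` (paths of
#'   written artifacts).
#' @export
runPipeline <- function(manifest, config = pipelineConfig(),
                        outputDir = NULL, includeSingleViews = FALSE,
                        verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  cohort <- loadCohort(manifest)
  n <- nROIs(cohort$timeSeries[[1]])
  if (config$rank > n)
    stop("configured rank (", config$rank, ") exceeds ROI count (", n, ")",
         call. = FALSE)
  fusion <- .fusionFromConfig(config)
  res <- loocvEvaluate(cohort$timeSeries, cohort$labels,
                       estimators = config$estimators,
                       grids = config$grids,
                       pThreshold = config$pThreshold,
                       fusion = fusion,
                       normalizeSlices = config$normalizeSlices,
                       includeSingleViews = includeSingleViews,
                       verbose = verbose)
  log <- foldLog(res$fused)
  modalParams <- vapply(config$estimators, function(e)
    .modalValue(log[[paste0("param", e)]]), numeric(1))
  names(modalParams) <- config$estimators
  files <- character(0)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    cfgTxt <- .configText(config)
    hash <- .configHash(cfgTxt)
    writePipelineConfig(config, file.path(outputDir, "config.txt"))
    removeProps <- modalParams[setdiff(config$estimators, "SR")]
    fusedDir <- file.path(outputDir, "fused")
    dir.create(fusedDir, showWarnings = FALSE)
    for (ts in cohort$timeSeries) {
      fb <- fuseSubject(ts, removeProps = removeProps,
                        srLambda = if ("SR" %in% config$estimators)
                          modalParams[["SR"]] else NULL,
                        config = fusion,
                        normalizeSlices = config$normalizeSlices,
                        estimators = config$estimators)
      f <- file.path(fusedDir, paste0(subjectID(ts), "_fused.tsv"))
      writeConnectivityMatrix(fb$fused, f, seed = config$seed,
                              configHash = hash)
      files <- c(files, f)
    }
    logFile <- file.path(outputDir, "fold_log.tsv")
    con <- file(logFile, "w")
    writeLines(.provenanceLine(config$seed, hash), con)
    close(con)
    suppressWarnings(utils::write.table(
      log, logFile, sep = "\t", row.names = FALSE, quote = FALSE,
      append = TRUE))
    reportFile <- file.path(outputDir, "report.txt")
    m <- metrics(res$fused)
    cc <- confusionCounts(res$fused)
    writeLines(c(.provenanceLine(config$seed, hash),
                 paste0(names(cc), " = ", cc),
                 paste0(names(m), " = ", sprintf("%.17g", m), " (",
                        sprintf("%.2f", 100 * m), "%)")),
               reportFile)
    files <- c(files, file.path(outputDir, "config.txt"), logFile,
               reportFile)
  }
  c(res, list(modalParams = modalParams, files = files))
}
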