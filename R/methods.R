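# Constructors, accessors and show methods.

#' Construct an ROITimeSeries
#'
#' @param data numeric matrix, timepoints x ROIs. Column names are used as
#'   ROI labels; default labels `ROI1..ROIn` are supplied when absent.
#' @param subjectID single character identifier.
#' @param roiLabels optional character vector overriding the column names.
#' @return A validated [ROITimeSeries-class] object.
#' @examples
#' ts <- ROITimeSeries(matrix(rnorm(60), 20, 3), subjectID = "sub01")
#' nROIs(ts)
#' @export
ROITimeSeries <- function(data, subjectID = "subject", roiLabels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.null(roiLabels)) colnames(data) <- roiLabels
  if (is.null(colnames(data)))
    colnames(data) <- paste0("ROI", seq_len(ncol(data)))
  new("ROITimeSeries", subjectID = as.character(subjectID), data = data)
}

#' Construct a ConnectivityMatrix
#'
#' Wraps an edge-weight matrix with provenance, enforcing symmetry (to
#' 1e-10), an exactly zero diagonal, and nonnegativity for MI networks.
#'
#' @param weights square numeric matrix.
#' @param method one of `"PC"`, `"SR"`, `"MI"`, `"CC"`, `"FUSED"`.
#' @param sparsityParam numeric provenance (SR lambda or removal proportion).
#' @param roiLabels optional ROI labels; defaults to existing dimnames.
#' @return A validated [ConnectivityMatrix-class].
#' @export
ConnectivityMatrix <- function(weights, method = "PC", sparsityParam = NA_real_,
                               roiLabels = NULL) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (is.null(roiLabels)) roiLabels <- colnames(weights)
  if (is.null(roiLabels)) roiLabels <- paste0("ROI", seq_len(ncol(weights)))
  dimnames(weights) <- list(roiLabels, roiLabels)
  new("ConnectivityMatrix", weights = weights, method = method,
      sparsityParam = as.numeric(sparsityParam))
}

#' @describeIn fbnfuse-accessors method for ROITimeSeries.
#' @export
setMethod("subjectID", "ROITimeSeries", function(object) object@subjectID)

#' @describeIn fbnfuse-accessors method for ROITimeSeries.
#' @export
setMethod("roiLabels", "ROITimeSeries",
          function(object) colnames(object@data))

#' @describeIn fbnfuse-accessors method for ROITimeSeries.
#' @export
setMethod("nROIs", "ROITimeSeries", function(object) ncol(object@data))

#' @describeIn fbnfuse-accessors method for ROITimeSeries.
#' @export
setMethod("tsData", "ROITimeSeries", function(object) object@data)

#' @describeIn fbnfuse-accessors method for ConnectivityMatrix.
#' @export
setMethod("weights", "ConnectivityMatrix", function(object) object@weights)

#' @describeIn fbnfuse-accessors method for ConnectivityMatrix.
#' @export
setMethod("roiLabels", "ConnectivityMatrix",
          function(object) colnames(object@weights))

#' @describeIn fbnfuse-accessors method for ConnectivityMatrix.
#' @export
setMethod("nROIs", "ConnectivityMatrix", function(object) ncol(object@weights))

#' @describeIn fbnfuse-accessors method for ConnectivityMatrix.
#' @export
setMethod("estimationMethod", "ConnectivityMatrix",
          function(object) object@method)

#' @describeIn fbnfuse-accessors method for ConnectivityMatrix.
#' @export
setMethod("sparsityParam", "ConnectivityMatrix",
          function(object) object@sparsityParam)

#' @describeIn fbnfuse-accessors method for ConnectivityTensor.
#' @export
setMethod("nSlices", "ConnectivityTensor", function(object) dim(object@data)[3])

#' @describeIn fbnfuse-accessors method for ConnectivityTensor.
#' @export
setMethod("nROIs", "ConnectivityTensor", function(object) dim(object@data)[1])

#' @describeIn fbnfuse-accessors method for ConnectivityTensor.
#' @export
setMethod("roiLabels", "ConnectivityTensor", function(object) object@roiLabels)

#' @describeIn fbnfuse-accessors method for ConnectivityTensor.
#' @export
setMethod("tensorData", "ConnectivityTensor", function(object) object@data)

#' @describeIn fbnfuse-accessors method for JointEmbedding.
#' @export
setMethod("embeddingFactor", "JointEmbedding", function(object) object@P)

#' @describeIn fbnfuse-accessors method for JointEmbedding.
#' @export
setMethod("coreSlices", "JointEmbedding", function(object) object@R)

#' @describeIn fbnfuse-accessors method for JointEmbedding.
#' @export
setMethod("fitTrace", "JointEmbedding", function(object) object@fitTrace)

#' @describeIn fbnfuse-accessors method for JointEmbedding.
#' @export
setMethod("converged", "JointEmbedding", function(object) object@converged)

#' @describeIn fbnfuse-accessors method for CentralityVector.
#' @export
setMethod("centralityScores", "CentralityVector",
          function(object) object@scores)

#' @describeIn fbnfuse-accessors method for MetricsReport.
#' @export
setMethod("metrics", "MetricsReport", function(object) object@metrics)

#' @describeIn fbnfuse-accessors method for MetricsReport.
#' @export
setMethod("confusionCounts", "MetricsReport", function(object)
  c(TP = object@TP, TN = object@TN, FP = object@FP, FN = object@FN))

#' @describeIn fbnfuse-accessors method for MetricsReport.
#' @export
setMethod("foldLog", "MetricsReport", function(object) object@foldLog)

setMethod("show", "ROITimeSeries", function(object) {
  cat("ROITimeSeries '", object@subjectID, "': ",
      nrow(object@data), " timepoints x ", ncol(object@data), " ROIs\n",
      sep = "")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  nz <- sum(object@weights[upper.tri(object@weights)] != 0)
  cat("ConnectivityMatrix (", object@method, "): ",
      nROIs(object), " ROIs, ", nz, " nonzero edges",
      if (!is.na(object@sparsityParam))
        paste0(", sparsity parameter ", signif(object@sparsityParam, 4)),
      "\n", sep = "")
})

setMethod("show", "ConnectivityTensor", function(object) {
  cat("ConnectivityTensor: ", nROIs(object), " x ", nROIs(object), " x ",
      nSlices(object), " [", paste(object@methods, collapse = ", "), "]",
      if (object@normalized) ", slices normalized to unit Frobenius norm",
      "\n", sep = "")
})

setMethod("show", "JointEmbedding", function(object) {
  cat("JointEmbedding: ", nrow(object@P), " ROIs x rank ", ncol(object@P),
      ", ", length(object@R), " core slice(s); ",
      object@iterationsRun, " sweep(s), ",
      if (object@converged) "converged" else "not converged",
      "; final fit ", signif(utils::tail(object@fitTrace, 1), 6), "\n",
      sep = "")
})

setMethod("show", "CentralityVector", function(object) {
  cat("CentralityVector: ", length(object@scores), " nodes, eigenvalue ",
      signif(object@eigenvalue, 6), "\n", sep = "")
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport (positive class = ASD)\n")
  cat("  TP=", object@TP, " TN=", object@TN, " FP=", object@FP,
      " FN=", object@FN, "\n", sep = "")
  m <- object@metrics
  cat(" ", paste(sprintf("%s=%.2f%%", names(m), 100 * m), collapse = " "),
      "\n")
  if (length(object@undefined))
    cat("  undefined:", paste(object@undefined, collapse = ", "), "\n")
  if (nrow(object@foldLog))
    cat("  folds:", nrow(object@foldLog), "\n")
})
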