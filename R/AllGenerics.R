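#' @name fbnfuse-accessors
#' @title Accessors for fbnfuse classes
#' @description Accessor generics for the package's S4 containers. Use these
#'   instead of reaching into slots.
#' @param object an fbnfuse S4 object.
#' @return The requested component; see the individual methods.
NULL

#' @describeIn fbnfuse-accessors subject identifier of a time-series set.
#' @export
setGeneric("subjectID", function(object) standardGeneric("subjectID"))

#' @describeIn fbnfuse-accessors ROI labels.
#' @export
setGeneric("roiLabels", function(object) standardGeneric("roiLabels"))

#' @describeIn fbnfuse-accessors number of ROIs.
#' @export
setGeneric("nROIs", function(object) standardGeneric("nROIs"))

#' @describeIn fbnfuse-accessors timepoints x ROIs signal matrix.
#' @export
setGeneric("tsData", function(object) standardGeneric("tsData"))

#' @describeIn fbnfuse-accessors edge-weight matrix of a network.
#' @export
setGeneric("weights", function(object) standardGeneric("weights"))

#' @describeIn fbnfuse-accessors estimation method label.
#' @export
setGeneric("estimationMethod",
           function(object) standardGeneric("estimationMethod"))

#' @describeIn fbnfuse-accessors sparsity parameter provenance.
#' @export
setGeneric("sparsityParam", function(object) standardGeneric("sparsityParam"))

#' @describeIn fbnfuse-accessors number of tensor slices.
#' @export
setGeneric("nSlices", function(object) standardGeneric("nSlices"))

#' @describeIn fbnfuse-accessors tensor slices as an n x n x m array.
#' @export
setGeneric("tensorData", function(object) standardGeneric("tensorData"))

#' @describeIn fbnfuse-accessors shared embedding factor P (n x r).
#' @export
setGeneric("embeddingFactor",
           function(object) standardGeneric("embeddingFactor"))

#' @describeIn fbnfuse-accessors list of core slices R(k).
#' @export
setGeneric("coreSlices", function(object) standardGeneric("coreSlices"))

#' @describeIn fbnfuse-accessors per-sweep normalized residual trace.
#' @export
setGeneric("fitTrace", function(object) standardGeneric("fitTrace"))

#' @describeIn fbnfuse-accessors convergence flag of a fitted embedding.
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @describeIn fbnfuse-accessors centrality scores.
#' @export
setGeneric("centralityScores",
           function(object) standardGeneric("centralityScores"))

#' @describeIn fbnfuse-accessors named metric vector of a report.
#' @export
setGeneric("metrics", function(object) standardGeneric("metrics"))

#' @describeIn fbnfuse-accessors confusion counts (TP, TN, FP, FN).
#' @export
setGeneric("confusionCounts",
           function(object) standardGeneric("confusionCounts"))

#' @describeIn fbnfuse-accessors per-fold log of a cross-validated report.
#' @export
setGeneric("foldLog", function(object) standardGeneric("foldLog"))
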