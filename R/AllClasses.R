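#' ROITimeSeries: one subject's ROI BOLD signals
#'
#' Container for a single subject's region-of-interest (ROI) time series: a
#' numeric matrix with one row per acquisition timepoint and one column per
#' ROI. Validity requires at least 3 timepoints, at least 2 ROIs, finite
#' values and no constant (zero-variance) ROI column.
#'
#' @slot subjectID single character subject identifier.
#' @slot data numeric matrix, timepoints x ROIs, with ROI labels as colnames.
#' @seealso [ROITimeSeries()] for construction, [readTimeSeries()] to load
#'   from file.
#' @export
setClass("ROITimeSeries",
  representation(subjectID = "character", data = "matrix"),
  validity = function(object) {
    X <- object@data
    if (length(object@subjectID) != 1L || is.na(object@subjectID))
      return("subjectID must be a single non-NA string")
    if (!is.numeric(X)) return("data must be numeric")
    if (nrow(X) < 3L) return("need at least 3 timepoints")
    if (ncol(X) < 2L) return("need at least 2 ROIs")
    if (!all(is.finite(X))) return("data contains non-finite values")
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      bad <- colnames(X)[which(sds == 0)[1]]
      if (is.null(bad)) bad <- which(sds == 0)[1]
      return(paste0("constant (zero-variance) ROI column: ", bad))
    }
    TRUE
  }
)

#' ConnectivityMatrix: one estimated functional brain network
#'
#' A symmetric, zero-diagonal, finite n x n edge-weight matrix with method
#' provenance. Mutual-information networks must additionally be entrywise
#' nonnegative.
#'
#' @slot weights numeric n x n matrix with ROI labels as dimnames.
#' @slot method one of `"PC"`, `"SR"`, `"MI"`, `"CC"`, `"FUSED"`.
#' @slot sparsityParam numeric; the SR regularization lambda, the removal
#'   proportion applied by [proportionalThreshold()], or `NA` when dense.
#' @export
setClass("ConnectivityMatrix",
  representation(weights = "matrix", method = "character",
                 sparsityParam = "numeric"),
  validity = function(object) {
    W <- object@weights
    if (!object@method %in% c("PC", "SR", "MI", "CC", "FUSED"))
      return("method must be one of PC, SR, MI, CC, FUSED")
    if (!is.numeric(W) || nrow(W) != ncol(W))
      return("weights must be a square numeric matrix")
    if (!all(is.finite(W))) return("weights contain non-finite values")
    if (max(abs(W - t(W))) > 1e-10) return("weights not symmetric to 1e-10")
    if (any(diag(W) != 0)) return("diagonal must be exactly zero")
    if (object@method == "MI" && any(W < 0))
      return("MI weights must be nonnegative")
    TRUE
  }
)

#' ConnectivityTensor: stacked multiview networks
#'
#' An n x n x m array whose frontal slices are same-order connectivity
#' matrices (one per view). Slices must be symmetric and finite; pipeline
#' tensors built from [ConnectivityMatrix] objects inherit zero diagonals,
#' while synthetic low-rank fixtures may carry nonzero diagonals.
#'
#' @slot data numeric array, n x n x m.
#' @slot roiLabels character vector of ROI labels (length n).
#' @slot methods character vector (length m) recording slice provenance.
#' @slot normalized logical; were slices rescaled to unit Frobenius norm?
#' @export
setClass("ConnectivityTensor",
  representation(data = "array", roiLabels = "character",
                 methods = "character", normalized = "logical"),
  validity = function(object) {
    A <- object@data
    if (length(dim(A)) != 3L) return("data must be a 3-d array")
    n <- dim(A)[1]
    if (dim(A)[2] != n) return("slices must be square")
    m <- dim(A)[3]
    if (m < 1L) return("need at least one slice")
    if (!all(is.finite(A))) return("tensor contains non-finite values")
    for (k in seq_len(m)) {
      if (max(abs(A[, , k] - t(A[, , k]))) > 1e-10)
        return(paste0("slice ", k, " is not symmetric"))
    }
    if (length(object@roiLabels) != n) return("roiLabels length must equal n")
    if (length(object@methods) != m) return("methods length must equal m")
    if (length(object@normalized) != 1L) return("normalized must be a flag")
    TRUE
  }
)

#' FusionConfig: parameters of the joint-embedding factorization
#'
#' @slot alpha nonnegative regularization weight on the core slices
#'   (default 10, the value at which classification performance peaked in the
#'   sensitivity analysis).
#' @slot rank embedding dimension r (default 50; must satisfy r <= n at use).
#' @slot tMax maximum number of alternating sweeps (default 100).
#' @slot epsilon convergence tolerance on the change in normalized fit
#'   between sweeps (default 1e-5).
#' @slot seed integer seed for the random core-slice initialization.
#' @slot reconMode `"pearson"` (default) or `"inner"`; see
#'   [reconstructFusedFBN()].
#' @slot reorthonormalize logical; re-orthonormalize the embedding by thin QR
#'   after each update (off by default, matching the plain ALS iteration).
#' @export
setClass("FusionConfig",
  representation(alpha = "numeric", rank = "integer", tMax = "integer",
                 epsilon = "numeric", seed = "integer", reconMode = "character",
                 reorthonormalize = "logical"),
  validity = function(object) {
    if (object@alpha < 0) return("alpha must be nonnegative")
    if (object@rank < 1L) return("rank must be a positive integer")
    if (object@tMax < 1L) return("tMax must be a positive integer")
    if (object@epsilon <= 0) return("epsilon must be positive")
    if (!object@reconMode %in% c("pearson", "inner"))
      return("reconMode must be 'pearson' or 'inner'")
    TRUE
  }
)

#' JointEmbedding: the fitted shared factor and core slices
#'
#' Result of [rescalALS()]: the shared ROI embedding P (n x r; row i is the
#' latent representation of ROI i common to all views), the per-view core
#' slices R(k) (r x r), and the per-sweep normalized-residual trace.
#'
#' @slot P numeric n x r matrix with ROI labels as rownames.
#' @slot R list of m numeric r x r core matrices.
#' @slot fitTrace numeric vector of per-sweep normalized residuals.
#' @slot iterationsRun number of sweeps performed.
#' @slot converged logical; did the trace change fall below epsilon?
#' @slot config the [FusionConfig] used.
#' @export
setClass("JointEmbedding",
  representation(P = "matrix", R = "list", fitTrace = "numeric",
                 iterationsRun = "integer", converged = "logical",
                 config = "FusionConfig"),
  validity = function(object) {
    if (any(object@fitTrace < 0)) return("fitTrace values must be >= 0")
    if (length(object@fitTrace) > 0 &&
        utils::tail(object@fitTrace, 1) > object@fitTrace[1] + 1e-12)
      return("final fit exceeds initial fit")
    if (ncol(object@P) != object@config@rank)
      return("P column count does not match configured rank")
    for (Rk in object@R) {
      if (!all(dim(Rk) == c(object@config@rank, object@config@rank)))
        return("core slice dimensions do not match configured rank")
    }
    TRUE
  }
)

#' CentralityVector: eigenvector centrality of a network
#'
#' @slot scores unit-norm numeric vector; sign fixed so the largest-magnitude
#'   entry is positive.
#' @slot eigenvalue the associated (algebraically largest) eigenvalue.
#' @export
setClass("CentralityVector",
  representation(scores = "numeric", eigenvalue = "numeric"),
  validity = function(object) {
    if (abs(sqrt(sum(object@scores^2)) - 1) > 1e-8)
      return("scores must have unit l2 norm")
    i <- which.max(abs(object@scores))
    if (object@scores[i] < 0)
      return("sign convention violated: largest-magnitude entry is negative")
    TRUE
  }
)

#' MetricsReport: confusion counts and classification metrics
#'
#' Confusion counts plus the seven evaluation metrics (ACC, SEN, SPE, BAC,
#' PPV, NPV, AUC) as proportions in [0, 1]. Undefined ratios (e.g. PPV with
#' no predicted positives) are stored as NaN and flagged in `undefined`
#' rather than silently zeroed.
#'
#' @slot TP,TN,FP,FN confusion counts (positive class = patient/ASD).
#' @slot metrics named numeric vector with elements ACC, SEN, SPE, BAC, PPV,
#'   NPV, AUC.
#' @slot undefined character vector naming metrics that were undefined.
#' @slot foldLog data.frame of per-fold bookkeeping (may have zero rows).
#' @export
setClass("MetricsReport",
  representation(TP = "integer", TN = "integer", FP = "integer",
                 FN = "integer", metrics = "numeric",
                 undefined = "character", foldLog = "data.frame"),
  validity = function(object) {
    need <- c("ACC", "SEN", "SPE", "BAC", "PPV", "NPV", "AUC")
    if (!all(need %in% names(object@metrics)))
      return("metrics must contain ACC, SEN, SPE, BAC, PPV, NPV, AUC")
    ok <- is.finite(object@metrics)
    if (any(object@metrics[ok] < -1e-12 | object@metrics[ok] > 1 + 1e-12))
      return("defined metrics must lie in [0, 1]")
    TRUE
  }
)
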