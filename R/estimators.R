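# Single-view FBN estimators.  All four operate on per-ROI centered,
# unit-l2-norm columns; Pearson correlation and equal-width-bin mutual
# information are invariant to that rescaling, and it makes the
# sparse-representation lambda grid scale-meaningful.

# Upper-triangle (i < j) index pairs in row-major order.
.upperPairs <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i = i, j = j)
}

#' Pearson-correlation functional brain network
#'
#' Full (marginal) correlation between every pair of ROI time series. The
#' densest and most widely used FBN estimator; the diagonal is zeroed so
#' self-loops never reach downstream fusion.
#'
#' @param ts an [ROITimeSeries-class] object.
#' @return A [ConnectivityMatrix-class] with `method = "PC"` and entries in
#'   \eqn{[-1, 1]}.
#' @examples
#' ts <- ROITimeSeries(matrix(rnorm(200), 50, 4))
#' pearsonFBN(ts)
#' @export
pearsonFBN <- function(ts) {
  stopifnot(is(ts, "ROITimeSeries"))
  W <- stats::cor(ts@data)
  diag(W) <- 0
  W <- (W + t(W)) / 2  # guard against asymmetric rounding
  ConnectivityMatrix(W, method = "PC", roiLabels = roiLabels(ts))
}

#' Raw sparse-representation coefficients
#'
#' Solves, for every ROI i, the l1-penalized least-squares regression of its
#' (standardized) signal on all other ROIs,
#' \deqn{\min_{w_{\cdot i}} \|x_i - \sum_{j \ne i} w_{ji} x_j\|_2^2 +
#'       \lambda \sum_{j \ne i} |w_{ji}|, \quad w_{ii} = 0,}
#' by warm-started cyclic coordinate descent (tolerance 1e-6 on the largest
#' coefficient change). The zero-diagonal constraint avoids the
#' trivial self-regression solution. Column i of the returned matrix holds
#' the coefficients of ROI i's regression; the matrix is generally
#' asymmetric.
#'
#' @param ts an [ROITimeSeries-class] object.
#' @param lambda nonnegative l1 penalty.
#' @param tol convergence tolerance on the max absolute coefficient change.
#' @param maxSweeps sweep budget for the coordinate-descent solver.
#' @return Numeric n x n matrix of raw regression coefficients (zero
#'   diagonal, not symmetrized).
#' @seealso [sparseRepresentationFBN()] for the symmetrized network.
#' @export
srCoefficients <- function(ts, lambda, tol = 1e-6, maxSweeps = 10000L) {
  stopifnot(is(ts, "ROITimeSeries"), lambda >= 0)
  X <- .standardizeColumns(ts@data)
  n <- ncol(X)
  G <- crossprod(X)
  W <- matrix(0, n, n, dimnames = list(roiLabels(ts), roiLabels(ts)))
  worst <- 0
  worstCol <- NA_integer_
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    Gi <- G[idx, idx, drop = FALSE]
    bi <- G[idx, i]
    # warm-start down a geometric lambda path from lambda_max (the smallest
    # penalty with an all-zero solution), the standard pathwise strategy for
    # correlated designs
    lamMax <- 2 * max(abs(bi))
    w <- rep(0, n - 1L)
    if (lambda < lamMax) {
      path <- exp(seq(log(lamMax), log(max(lambda, 1e-12)),
                      length.out = 8L))[-1]
      path[length(path)] <- lambda
      for (lam in path) {
        fit <- .lassoCD(Gi, bi, lam, tol, as.integer(maxSweeps), w)
        w <- fit$w
      }
    } else {
      fit <- .lassoCD(Gi, bi, lambda, tol, as.integer(maxSweeps), w)
      w <- fit$w
    }
    if (!fit$converged && fit$maxChange > worst) {
      worst <- fit$maxChange
      worstCol <- i
    }
    W[idx, i] <- w
  }
  if (!is.na(worstCol))
    stop("sparse-representation solver did not converge within ", maxSweeps,
         " sweeps; worst column ", roiLabels(ts)[worstCol],
         " with residual coefficient change ", signif(worst, 4),
         call. = FALSE)
  W
}

#' Sparse-representation functional brain network
#'
#' Partial-correlation-flavoured FBN: each ROI is regressed on all others
#' under an l1 sparsity penalty ([srCoefficients()]), and the asymmetric
#' coefficient matrix is symmetrized as \eqn{W \gets (W + W^\top)/2}.
#'
#' @inheritParams srCoefficients
#' @return A [ConnectivityMatrix-class] with `method = "SR"` and
#'   `sparsityParam = lambda`.
#' @examples
#' ts <- ROITimeSeries(matrix(rnorm(250), 50, 5))
#' sparseRepresentationFBN(ts, lambda = 0.25)
#' @export
sparseRepresentationFBN <- function(ts, lambda, tol = 1e-6,
                                    maxSweeps = 10000L) {
  W <- srCoefficients(ts, lambda, tol = tol, maxSweeps = maxSweeps)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  ConnectivityMatrix(W, method = "SR", sparsityParam = lambda,
                     roiLabels = roiLabels(ts))
}

# Equal-width bin index of a signal over its observed range.
.binIndices <- function(x, nBins) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(1L, length(x)))
  b <- findInterval(x, seq(r[1], r[2], length.out = nBins + 1L),
                    rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(b)
}

# Plug-in mutual information (nats) of two bin-index vectors, with the
# 0 * log(0) = 0 convention.
.binnedMI <- function(bi, bj, nBins) {
  joint <- tabulate((bi - 1L) * nBins + bj, nbins = nBins * nBins)
  v <- sum(joint)
  pxy <- joint / v
  px <- tabulate(bi, nbins = nBins) / v
  py <- tabulate(bj, nbins = nBins) / v
  # joint position (bi-1)*nBins + bj: bi varies slowest
  biIdx <- rep(seq_len(nBins), each = nBins)
  bjIdx <- rep(seq_len(nBins), times = nBins)
  keep <- pxy > 0
  sum(pxy[keep] * log(pxy[keep] / (px[biIdx[keep]] * py[bjIdx[keep]])))
}

#' Mutual-information functional brain network
#'
#' Histogram (plug-in) mutual information between every ROI pair, in nats.
#' Each signal is discretized into `nBins` equal-width bins over its observed
#' range (the bin counts are invariant to the package's per-ROI
#' standardization); the joint distribution is the normalized 2-d histogram
#' and \eqn{0 \log 0 = 0}. MI captures nonlinear dependence and is zero for
#' pairs whose binned distributions factorize.
#'
#' @param ts an [ROITimeSeries-class] object.
#' @param nBins number of equal-width bins per signal (>= 2). Default
#'   \eqn{\lceil\sqrt{v}\rceil} for v timepoints, the usual histogram rule.
#' @return A [ConnectivityMatrix-class] with `method = "MI"`; entries are
#'   nonnegative, diagonal zero.
#' @examples
#' ts <- ROITimeSeries(matrix(rnorm(400), 100, 4))
#' mutualInformationFBN(ts)
#' @export
mutualInformationFBN <- function(ts, nBins = NULL) {
  stopifnot(is(ts, "ROITimeSeries"))
  X <- .standardizeColumns(ts@data)
  v <- nrow(X)
  if (is.null(nBins)) nBins <- as.integer(ceiling(sqrt(v)))
  nBins <- as.integer(nBins)
  stopifnot(nBins >= 2L)
  n <- ncol(X)
  bins <- lapply(seq_len(n), function(j) .binIndices(X[, j], nBins))
  W <- matrix(0, n, n, dimnames = list(roiLabels(ts), roiLabels(ts)))
  pairs <- .upperPairs(n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    mi <- .binnedMI(bins[[i]], bins[[j]], nBins)
    W[i, j] <- W[j, i] <- max(mi, 0)  # clamp tiny negative rounding
  }
  ConnectivityMatrix(W, method = "MI", sparsityParam = as.numeric(nBins),
                     roiLabels = roiLabels(ts))
}

#' Correlation's-correlation (high-order) functional brain network
#'
#' Two-step estimator of high-order connectivity: (1) compute the low-order
#' Pearson network W with its diagonal kept at 1 (each ROI's self
#' correlation), so column i of W is ROI i's full connectivity profile;
#' (2) set \eqn{H_{ij}} to the Pearson correlation of columns i and j of W.
#' Two ROIs are strongly connected in H when they correlate with the rest of
#' the brain in the same way. The diagonal of H is zeroed.
#'
#' @param ts an [ROITimeSeries-class] object.
#' @return A [ConnectivityMatrix-class] with `method = "CC"`.
#' @examples
#' ts <- ROITimeSeries(matrix(rnorm(300), 50, 6))
#' correlationsCorrelationFBN(ts)
#' @export
correlationsCorrelationFBN <- function(ts) {
  stopifnot(is(ts, "ROITimeSeries"))
  W <- stats::cor(ts@data)  # diagonal is 1 by construction
  sds <- apply(W, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- roiLabels(ts)[which(sds == 0)[1]]
    stop("degenerate low-order connectivity profile (constant column of W) ",
         "for ROI ", bad, call. = FALSE)
  }
  H <- stats::cor(W)
  diag(H) <- 0
  H <- (H + t(H)) / 2
  ConnectivityMatrix(H, method = "CC", roiLabels = roiLabels(ts))
}

#' Proportional thresholding of a connectivity matrix
#'
#' Removes a fixed proportion of the weakest edges: exactly
#' \eqn{\lfloor p \cdot E \rfloor} of the \eqn{E = n(n-1)/2} upper-triangle
#' edges with the smallest absolute weight are zeroed (mirrored to the lower
#' triangle); surviving weights are unchanged. Large-magnitude negative
#' edges survive. Magnitude ties are broken by retaining the pair with the
#' smaller (i, j) row-major index.
#'
#' @param W a [ConnectivityMatrix-class].
#' @param removeProp proportion of edges to remove, in \eqn{[0, 1)}.
#' @return A [ConnectivityMatrix-class] with `sparsityParam = removeProp`.
#' @examples
#' ts <- ROITimeSeries(matrix(rnorm(200), 50, 4))
#' proportionalThreshold(pearsonFBN(ts), 0.5)
#' @export
proportionalThreshold <- function(W, removeProp) {
  stopifnot(is(W, "ConnectivityMatrix"))
  if (!is.numeric(removeProp) || length(removeProp) != 1L ||
      removeProp < 0 || removeProp >= 1)
    stop("removeProp must be a single number in [0, 1)", call. = FALSE)
  M <- W@weights
  n <- ncol(M)
  pairs <- .upperPairs(n)
  absw <- abs(M[pairs])
  E <- nrow(pairs)
  k <- floor(removeProp * E)
  if (k > 0) {
    # ascending magnitude; on ties remove the larger row-major index first
    ord <- order(absw, -seq_len(E))
    drop <- pairs[ord[seq_len(k)], , drop = FALSE]
    M[drop] <- 0
    M[drop[, c(2L, 1L), drop = FALSE]] <- 0
  }
  ConnectivityMatrix(M, method = W@method, sparsityParam = removeProp,
                     roiLabels = roiLabels(W))
}
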