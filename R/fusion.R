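# Multiview fusion: tensor stacking, regularized ALS bilinear factorization
# (shared factor P, per-view cores R(k)), fused-network reconstruction, and
# the eigenvector-centrality connection.

#' Fusion configuration
#'
#' Bundles the tunable parameters of the joint-embedding factorization.
#' Defaults follow the reported sensitivity analysis: `alpha = 10` and
#' `rank = 50` gave the best classification performance on the 116-ROI
#' cohort; for smaller parcellations choose a rank of roughly 0.4 n.
#'
#' @param alpha nonnegative regularization weight on the core slices.
#' @param rank embedding dimension r (must satisfy r <= n when fitting).
#' @param tMax maximum number of alternating sweeps.
#' @param epsilon convergence tolerance on the between-sweep change of the
#'   normalized residual.
#' @param seed integer seed for the random standard-normal core
#'   initialization (recorded for reproducibility).
#' @param reconMode `"pearson"` (default) correlates embedded ROI rows;
#'   `"inner"` uses the Gram matrix P P'.
#' @param reorthonormalize apply a thin QR to P after each update. Off by
#'   default (the plain ALS iteration); switch on to realize the
#'   eigenvector-centrality equivalence exactly.
#' @return A [FusionConfig-class] object.
#' @examples
#' FusionConfig(alpha = 0, rank = 5)
#' @export
FusionConfig <- function(alpha = 10, rank = 50L, tMax = 100L, epsilon = 1e-5,
                         seed = 1L, reconMode = "pearson",
                         reorthonormalize = FALSE) {
  new("FusionConfig", alpha = as.numeric(alpha), rank = as.integer(rank),
      tMax = as.integer(tMax), epsilon = as.numeric(epsilon),
      seed = as.integer(seed), reconMode = reconMode,
      reorthonormalize = isTRUE(reorthonormalize))
}

#' Stack connectivity matrices into a tensor
#'
#' Stacks m same-order networks into an n x n x m tensor, optionally
#' rescaling each slice to unit Frobenius norm so that views living on
#' different scales (e.g. mutual information vs. correlation) contribute
#' comparably to the least-squares objective.
#'
#' @param fbns list of [ConnectivityMatrix-class] objects sharing dimension
#'   and ROI labels.
#' @param normalize divide each slice by its Frobenius norm (default TRUE).
#' @param onZeroSlice what to do with an all-zero slice when normalizing:
#'   `"error"` (default) or `"keep"` (leave it as zeros with a warning; a
#'   zero view contributes nothing to the factorization objective).
#' @return A [ConnectivityTensor-class].
#' @examples
#' ts <- ROITimeSeries(matrix(rnorm(200), 50, 4))
#' stackTensor(list(pearsonFBN(ts), mutualInformationFBN(ts)))
#' @export
stackTensor <- function(fbns, normalize = TRUE,
                        onZeroSlice = c("error", "keep")) {
  onZeroSlice <- match.arg(onZeroSlice)
  stopifnot(is.list(fbns), length(fbns) >= 1L,
            all(vapply(fbns, is, logical(1), "ConnectivityMatrix")))
  labs <- roiLabels(fbns[[1]])
  n <- nROIs(fbns[[1]])
  m <- length(fbns)
  A <- array(0, dim = c(n, n, m))
  for (k in seq_len(m)) {
    if (nROIs(fbns[[k]]) != n)
      stop("slice ", k, " (", fbns[[k]]@method, ") has ", nROIs(fbns[[k]]),
           " ROIs, expected ", n, call. = FALSE)
    if (!identical(roiLabels(fbns[[k]]), labs))
      stop("slice ", k, " (", fbns[[k]]@method,
           ") has mismatched ROI labels", call. = FALSE)
    S <- fbns[[k]]@weights
    if (normalize) {
      nrm <- .frobenius(S)
      if (nrm == 0) {
        if (onZeroSlice == "error")
          stop("slice ", k, " (", fbns[[k]]@method,
               ") has zero Frobenius norm and cannot be normalized",
               call. = FALSE)
        warning("slice ", k, " (", fbns[[k]]@method,
                ") is all zero; kept unscaled", call. = FALSE)
      } else {
        S <- S / nrm
      }
    }
    A[, , k] <- S
  }
  new("ConnectivityTensor", data = A, roiLabels = labs,
      methods = vapply(fbns, estimationMethod, character(1)),
      normalized = isTRUE(normalize))
}

.tensorArray <- function(tensor) {
  if (is(tensor, "ConnectivityTensor")) tensor@data
  else if (is.array(tensor) && length(dim(tensor)) == 3L) tensor
  else stop("expected a ConnectivityTensor or an n x n x m array",
            call. = FALSE)
}

#' Spectral initialization of the joint embedding
#'
#' Columns are the orthonormal eigenvectors of
#' \eqn{\sum_k (A^{(k)} + A^{(k)\top})} belonging to its r largest-magnitude
#' eigenvalues (magnitude ties resolved toward the algebraically larger),
#' ordered accordingly, each sign-fixed so its largest-magnitude entry is
#' positive. Magnitude ordering keeps the negative-eigenvalue directions of
#' indefinite low-rank slices, so on a noiseless rank-r tensor the
#' initialization already spans the ground-truth factor.
#'
#' @param tensor a [ConnectivityTensor-class] or n x n x m array.
#' @param rank number of leading eigenvectors r (<= n).
#' @return Numeric n x r matrix with orthonormal columns.
#' @export
initEmbedding <- function(tensor, rank) {
  A <- .tensorArray(tensor)
  n <- dim(A)[1]
  rank <- as.integer(rank)
  stopifnot(rank >= 1L, rank <= n)
  S <- matrix(0, n, n)
  for (k in seq_len(dim(A)[3])) S <- S + A[, , k] + t(A[, , k])
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ord <- order(-abs(e$values))  # stable: magnitude ties keep algebraic order
  .signFixColumns(e$vectors[, ord[seq_len(rank)], drop = FALSE])
}

#' Core-slice update of the regularized ALS factorization
#'
#' For fixed P with thin SVD \eqn{P = U \Sigma V^\top}, each core slice is
#' the ridge-regularized least-squares solution
#' \deqn{R^{(k)} = V \left( S \circ (U^\top A^{(k)} U) \right) V^\top,
#'       \qquad S_{ij} = \frac{\sigma_i \sigma_j}
#'                            {\sigma_i^2 \sigma_j^2 + \alpha},}
#' the exact minimizer of
#' \eqn{\|A^{(k)} - P R P^\top\|_F^2 + \alpha \|R\|_F^2}. With orthonormal
#' P this reduces to \eqn{R^{(k)} = P^\top A^{(k)} P / (1 + \alpha)}.
#'
#' @param tensor a [ConnectivityTensor-class] or n x n x m array.
#' @param P numeric n x r matrix of full column rank.
#' @param alpha nonnegative regularization weight.
#' @return List of m numeric r x r core matrices.
#' @export
updateCore <- function(tensor, P, alpha) {
  A <- .tensorArray(tensor)
  stopifnot(is.matrix(P), nrow(P) == dim(A)[1], alpha >= 0)
  sv <- svd(P)
  if (alpha == 0 && min(sv$d) <= max(sv$d) * 1e-12)
    stop("P is rank deficient; core update is singular at alpha = 0",
         call. = FALSE)
  S <- outer(sv$d, sv$d) / (outer(sv$d, sv$d)^2 + alpha)
  lapply(seq_len(dim(A)[3]), function(k) {
    M <- S * (crossprod(sv$u, A[, , k]) %*% sv$u)
    sv$v %*% M %*% t(sv$v)
  })
}

#' Embedding update of the regularized ALS factorization
#'
#' The alternating-least-squares update of the shared factor,
#' \deqn{P \gets \Big[\textstyle\sum_k \big(A^{(k)} P R^{(k)\top} +
#'       A^{(k)\top} P R^{(k)}\big)\Big]
#'       \Big[\textstyle\sum_k \big(R^{(k)} R^{(k)\top} +
#'       R^{(k)\top} R^{(k)}\big) + \alpha I\Big]^{-1}.}
#' When `reorthonormalize` is on, the result is replaced by the orthonormal
#' factor of its thin QR decomposition (columns sign-fixed).
#'
#' @param tensor a [ConnectivityTensor-class] or n x n x m array.
#' @param P current n x r embedding.
#' @param R list of m r x r core slices.
#' @param alpha nonnegative regularization weight.
#' @param reorthonormalize logical.
#' @return Updated n x r matrix.
#' @export
updateEmbedding <- function(tensor, P, R, alpha, reorthonormalize = FALSE) {
  A <- .tensorArray(tensor)
  r <- ncol(P)
  num <- matrix(0, nrow(P), r)
  den <- diag(alpha, r)
  for (k in seq_along(R)) {
    Ak <- A[, , k]
    Rk <- R[[k]]
    num <- num + Ak %*% P %*% t(Rk) + t(Ak) %*% P %*% Rk
    den <- den + Rk %*% t(Rk) + t(Rk) %*% Rk
  }
  Pn <- tryCatch(t(solve(den, t(num))), error = function(e)
    stop("singular system in embedding update (alpha = ", alpha,
         "): ", conditionMessage(e), call. = FALSE))
  if (reorthonormalize) {
    Pn <- .signFixColumns(qr.Q(qr(Pn))[, seq_len(r), drop = FALSE])
  }
  Pn
}

.tensorFit <- function(A, P, R) {
  chi <- 0
  res <- 0
  for (k in seq_along(R)) {
    res <- res + sum((A[, , k] - P %*% R[[k]] %*% t(P))^2)
  }
  chiMat <- apply(A, c(1, 2), sum)
  res / sum(chiMat^2)
}

#' Regularized alternating-least-squares joint embedding
#'
#' Fits the bilinear factorization \eqn{A^{(k)} \approx P R^{(k)} P^\top}
#' shared across all tensor slices by alternating [updateEmbedding()] and
#' [updateCore()]. P is initialized spectrally ([initEmbedding()]) and the
#' cores by seeded standard-normal draws. After each sweep the normalized
#' residual
#' \eqn{\mathrm{fit} = \sum_k \|A^{(k)} - P R^{(k)} P^\top\|_F^2 /
#'       \|\chi\|_F^2} (with \eqn{\chi = \sum_k A^{(k)}}) is recorded;
#' iteration stops when the between-sweep change drops below
#' `epsilon` or `tMax` sweeps have run.
#'
#' @param tensor a [ConnectivityTensor-class] or n x n x m array.
#' @param config a [FusionConfig-class]; `config@rank` must not exceed n.
#' @return A [JointEmbedding-class] with the fit trace.
#' @examples
#' sim <- simulateTensor(SyntheticTensorSpec(n = 12, rank = 3, m = 2,
#'                                           noiseSd = 0, seed = 7))
#' emb <- rescalALS(sim$tensor, FusionConfig(alpha = 0, rank = 3))
#' tail(fitTrace(emb), 1)  # ~ 0: exact low-rank tensor is representable
#' @export
rescalALS <- function(tensor, config = FusionConfig()) {
  stopifnot(is(config, "FusionConfig"))
  A <- .tensorArray(tensor)
  n <- dim(A)[1]
  m <- dim(A)[3]
  r <- config@rank
  if (r > n) stop("rank (", r, ") exceeds number of ROIs (", n, ")",
                  call. = FALSE)
  P <- initEmbedding(A, r)
  R <- .withSeed(config@seed,
                 lapply(seq_len(m), function(k) matrix(rnorm(r * r), r, r)))
  # trace[1] is the fit at initialization; one entry is appended per sweep
  trace <- .tensorFit(A, P, R)
  convergedFlag <- FALSE
  t <- 0L
  best <- list(P = P, R = R, fit = trace[1], t = 0L)
  while (t < config@tMax) {
    t <- t + 1L
    P <- updateEmbedding(A, P, R, config@alpha,
                         reorthonormalize = config@reorthonormalize)
    R <- updateCore(A, P, config@alpha)
    fit <- .tensorFit(A, P, R)
    if (!is.finite(fit))
      stop("non-finite fit at sweep ", t,
           "; the factorization diverged (alpha = ", config@alpha, ")",
           call. = FALSE)
    trace <- c(trace, fit)
    if (fit <= best$fit)
      best <- list(P = P, R = R, fit = fit, t = t)
    if (abs(trace[t + 1L] - trace[t]) < config@epsilon) {
      convergedFlag <- TRUE
      break
    }
  }
  # The alternating update of P is not an exact descent step, so on noisy
  # or strongly regularized problems the residual can drift upward late in
  # the run; keep the best-fit iterate in that case.
  if (trace[t + 1L] > trace[1L] + 1e-12) {
    warning("fit increased over the run; returning the best-fit sweep (",
            best$t, " of ", t, ")", call. = FALSE)
    P <- best$P
    R <- best$R
    trace <- trace[seq_len(best$t + 1L)]
    t <- best$t
    convergedFlag <- FALSE
  }
  if (is(tensor, "ConnectivityTensor"))
    rownames(P) <- tensor@roiLabels
  new("JointEmbedding", P = P, R = R, fitTrace = trace,
      iterationsRun = t, converged = convergedFlag, config = config)
}

#' Reconstruct the fused network from a joint embedding
#'
#' `mode = "pearson"` (default) sets \eqn{W_{ij}} to the Pearson correlation
#' of embedding rows \eqn{p_i} and \eqn{p_j} — two ROIs are connected in the
#' fused network when their latent multiview profiles co-vary. `mode =
#' "inner"` uses the Gram matrix \eqn{W = P P^\top} instead. Both zero the
#' diagonal.
#'
#' @param emb a [JointEmbedding-class].
#' @param mode `"pearson"` or `"inner"`; defaults to the mode recorded in
#'   the embedding's config.
#' @return A [ConnectivityMatrix-class] with `method = "FUSED"`.
#' @export
reconstructFusedFBN <- function(emb, mode = NULL) {
  stopifnot(is(emb, "JointEmbedding"))
  if (is.null(mode)) mode <- emb@config@reconMode
  mode <- match.arg(mode, c("pearson", "inner"))
  P <- emb@P
  if (mode == "pearson") {
    if (ncol(P) < 2L)
      stop("pearson reconstruction needs embedding rank >= 2", call. = FALSE)
    sds <- apply(P, 1, stats::sd)
    if (any(sds == 0)) {
      lbl <- rownames(P)[which(sds == 0)[1]]
      if (is.null(lbl)) lbl <- which(sds == 0)[1]
      stop("constant embedding row for ROI ", lbl,
           "; pearson reconstruction undefined", call. = FALSE)
    }
    W <- stats::cor(t(P))
  } else {
    W <- tcrossprod(P)
  }
  diag(W) <- 0
  W <- (W + t(W)) / 2
  labs <- rownames(P)
  ConnectivityMatrix(W, method = "FUSED", roiLabels = labs)
}

#' Eigenvector centrality of a symmetric network
#'
#' Returns the unit-norm eigenvector belonging to the algebraically largest
#' eigenvalue of the weight matrix, sign-fixed so its largest-magnitude
#' entry is positive, together with the eigenvalue. For a rank-1 joint
#' embedding of a single network the learned factor coincides with this
#' vector — the centrality reading of the fusion model.
#'
#' @param W a [ConnectivityMatrix-class] or symmetric numeric matrix.
#' @return A [CentralityVector-class].
#' @examples
#' K4 <- ConnectivityMatrix(matrix(1, 4, 4) - diag(4))
#' eigenvectorCentrality(K4)  # all nodes equivalent, eigenvalue 3
#' @export
eigenvectorCentrality <- function(W) {
  M <- if (is(W, "ConnectivityMatrix")) W@weights else as.matrix(W)
  if (!.isSymmetric(M)) stop("W must be symmetric", call. = FALSE)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (length(e$values) > 1L && abs(e$values[1] - e$values[2]) <= 1e-10)
    warning("top eigenvalue is tied within 1e-10; ",
            "returning the sign-fixed first eigenvector", call. = FALSE)
  x <- e$vectors[, 1L]
  x <- x / sqrt(sum(x^2))
  i <- which.max(abs(x))
  if (x[i] < 0) x <- -x
  new("CentralityVector", scores = as.numeric(x),
      eigenvalue = e$values[1L])
}

#' One-call multiview fusion for a single subject
#'
#' Estimates the requested single-view networks from a subject's time
#' series, applies proportional thresholding (PC/MI/CC) or the SR lambda,
#' stacks, factors and reconstructs the fused network.
#'
#' @param ts an [ROITimeSeries-class].
#' @param removeProps named numeric vector of removal proportions for the
#'   dense views, e.g. `c(PC = 0, MI = 0, CC = 0)`; views absent from the
#'   vector are kept dense.
#' @param srLambda l1 penalty of the sparse-representation view; `NULL`
#'   drops the view.
#' @param config a [FusionConfig-class].
#' @param normalizeSlices rescale slices to unit Frobenius norm before
#'   stacking.
#' @param estimators character subset of `c("PC","SR","MI","CC")` selecting
#'   the views, in slice order.
#' @return A list with elements `fused` ([ConnectivityMatrix-class]),
#'   `embedding` ([JointEmbedding-class]) and `views` (list of the
#'   thresholded single-view networks).
#' @export
fuseSubject <- function(ts, removeProps = c(PC = 0, MI = 0, CC = 0),
                        srLambda = 1, config = FusionConfig(),
                        normalizeSlices = TRUE,
                        estimators = c("PC", "SR", "MI", "CC")) {
  views <- list()
  for (est in estimators) {
    fbn <- switch(est,
      PC = pearsonFBN(ts),
      SR = sparseRepresentationFBN(ts, srLambda),
      MI = mutualInformationFBN(ts),
      CC = correlationsCorrelationFBN(ts),
      stop("unknown estimator: ", est, call. = FALSE))
    if (est != "SR" && est %in% names(removeProps) &&
        removeProps[[est]] > 0)
      fbn <- proportionalThreshold(fbn, removeProps[[est]])
    views[[est]] <- fbn
  }
  tensor <- stackTensor(views, normalize = normalizeSlices,
                          onZeroSlice = "keep")
  emb <- rescalALS(tensor, config)
  list(fused = reconstructFusedFBN(emb), embedding = emb, views = views)
}

#' Averaging fusion baseline
#'
#' Entrywise mean of the input networks — the naive fusion baseline against
#' which the joint-embedding fusion is compared. Averaging signed edge
#' weights cancels oppositely signed connections, which is the failure mode
#' the embedding fusion is designed to avoid.
#'
#' @param fbns list of [ConnectivityMatrix-class] objects sharing order.
#' @return A [ConnectivityMatrix-class] with `method = "FUSED"`.
#' @export
averagingFusion <- function(fbns) {
  tens <- stackTensor(fbns, normalize = FALSE)
  W <- apply(tens@data, c(1, 2), mean)
  diag(W) <- 0
  ConnectivityMatrix((W + t(W)) / 2, method = "FUSED",
                     roiLabels = tens@roiLabels)
}
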