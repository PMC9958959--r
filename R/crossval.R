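# Nested leave-one-out protocol: inner frequency-based parameter selection,
# outer LOOCV with t-test feature selection and a linear SVM.

#' Default per-estimator parameter grids
#'
#' Removal-proportion grid `0, 0.1, ..., 0.9, 0.99` for the dense views
#' (PC, MI, CC) and the lambda grid \eqn{2^{-5}, ..., 2^{5}} for the
#' sparse-representation view.
#'
#' @return Named list of numeric grids (`PC`, `SR`, `MI`, `CC`).
#' @export
defaultGrids <- function() {
  prop <- c(seq(0, 0.9, by = 0.1), 0.99)
  list(PC = prop, SR = 2^(-5:5), MI = prop, CC = prop)
}

# rebuild a symmetric zero-diagonal matrix from a row-major upper-triangle
# vector
.matFromUpper <- function(v, n, labels = NULL) {
  M <- matrix(0, n, n)
  pairs <- .upperPairs(n)
  M[pairs] <- v
  M[pairs[, c(2L, 1L)]] <- v
  if (!is.null(labels)) dimnames(M) <- list(labels, labels)
  M
}

.majorityClass <- function(y) {
  tab <- table(factor(y, levels = c("NC", "ASD")))
  if (tab[["ASD"]] > tab[["NC"]]) "ASD" else "NC"
}

# one train/predict step: t-test selection on the training rows, linear SVM,
# prediction of the held-out rows.  Falls back to the training-majority
# class (score 0) when no feature survives selection or a class is too
# small for the t-test.
.foldPredict <- function(X, y, trainIdx, testIdx, pThreshold) {
  yTr <- y[trainIdx]
  fallback <- function(mask) {
    maj <- .majorityClass(yTr)
    list(labels = factor(rep(maj, length(testIdx)),
                         levels = c("NC", "ASD")),
         scores = rep(0, length(testIdx)), mask = mask, fallback = TRUE)
  }
  if (min(table(factor(yTr, levels = c("NC", "ASD")))) < 2L)
    return(fallback(logical(ncol(X))))
  mask <- ttestSelect(X[trainIdx, , drop = FALSE], yTr, pThreshold)
  if (!any(mask)) return(fallback(mask))
  fit <- fitPredictLinearSVM(X[trainIdx, mask, drop = FALSE], yTr,
                             X[testIdx, mask, drop = FALSE])
  list(labels = fit$labels, scores = fit$scores, mask = mask,
       fallback = FALSE)
}

#' Frequency-based inner parameter selection
#'
#' Inner leave-one-out loop over the training subjects: in each cycle one
#' subject is held out, every candidate parameter is scored by the accuracy
#' of a t-test + linear-SVM classifier (trained on the remaining subjects)
#' on that subject, and the best-scoring parameter is recorded (accuracy
#' ties go to the earlier grid position). The parameter recorded most often
#' across cycles is returned, again with ties broken by grid order.
#'
#' @param featureProvider function mapping a grid value to the subjects x
#'   features matrix for that parameter (rows aligned with `labels`).
#' @param labels class labels of the training subjects.
#' @param grid nonempty numeric vector of candidate parameters.
#' @param pThreshold t-test selection threshold used inside each cycle.
#' @return The chosen grid value, with attributes `"index"` (grid position)
#'   and `"frequency"` (per-grid-value win counts).
#' @export
innerParameterSelection <- function(featureProvider, labels, grid,
                                    pThreshold = 0.001) {
  stopifnot(length(grid) >= 1L)
  y <- .normalizeLabels(labels)
  N <- length(y)
  if (N < 3L) stop("need at least 3 subjects for inner selection",
                   call. = FALSE)
  Xs <- lapply(grid, featureProvider)
  winners <- integer(N)
  anyDistinction <- FALSE
  for (i in seq_len(N)) {
    train <- setdiff(seq_len(N), i)
    acc <- vapply(seq_along(grid), function(g) {
      pr <- .foldPredict(Xs[[g]], y, train, i, pThreshold)
      as.numeric(pr$labels == y[i])
    }, numeric(1))
    if (length(unique(acc)) > 1L) anyDistinction <- TRUE
    winners[i] <- which.max(acc)
  }
  freq <- tabulate(winners, nbins = length(grid))
  if (!anyDistinction) {
    warning("all parameters achieved identical inner accuracies; ",
            "returning the first grid element", call. = FALSE)
    chosen <- 1L
  } else {
    chosen <- which.max(freq)
  }
  out <- grid[chosen]
  attr(out, "index") <- chosen
  attr(out, "frequency") <- freq
  out
}

# Precompute, for every estimator and grid value, the subjects x features
# matrix of upper-triangle weights.  Label-free, so it may be shared across
# folds and with permuted-label runs.
.precomputeViewFeatures <- function(tsList, estimators, grids,
                                    verbose = FALSE) {
  n <- nROIs(tsList[[1]])
  nFeat <- n * (n - 1L) / 2L
  N <- length(tsList)
  out <- list()
  dense <- list()
  for (est in intersect(c("PC", "MI", "CC"), estimators)) {
    dense[[est]] <- lapply(tsList, function(ts) switch(est,
      PC = pearsonFBN(ts), MI = mutualInformationFBN(ts),
      CC = correlationsCorrelationFBN(ts)))
  }
  for (est in estimators) {
    grid <- grids[[est]]
    mats <- vector("list", length(grid))
    for (g in seq_along(grid)) {
      X <- matrix(0, N, nFeat)
      for (s in seq_len(N)) {
        fbn <- if (est == "SR") {
          sparseRepresentationFBN(tsList[[s]], grid[g])
        } else if (grid[g] > 0) {
          proportionalThreshold(dense[[est]][[s]], grid[g])
        } else dense[[est]][[s]]
        X[s, ] <- vectorizeUpper(fbn)
      }
      mats[[g]] <- X
    }
    out[[est]] <- mats
    if (verbose) message("precomputed ", est, " features (",
                         length(grid), " grid values)")
  }
  out
}

# Leave-two-out correctness matrix for one feature matrix: C[i, o] = 1 when
# subject i is predicted correctly by the classifier trained on all
# subjects except {i, o}.  In the nested protocol, fold o's inner cycle i
# and fold i's inner cycle o share this training set, so one fit serves
# both; t-test statistics are obtained incrementally from class totals.
.pairwiseCorrect <- function(X, y, pThreshold) {
  N <- nrow(X)
  isPos <- y == "ASD"
  S1 <- colSums(X[isPos, , drop = FALSE])
  Q1 <- colSums(X[isPos, , drop = FALSE]^2)
  S0 <- colSums(X[!isPos, , drop = FALSE])
  Q0 <- colSums(X[!isPos, , drop = FALSE]^2)
  n1All <- sum(isPos); n0All <- N - n1All
  C <- matrix(NA, N, N)
  for (a in seq_len(N - 1L)) {
    for (b in (a + 1L):N) {
      s1 <- S1; q1 <- Q1; s0 <- S0; q0 <- Q0
      n1 <- n1All; n0 <- n0All
      for (r in c(a, b)) {
        if (isPos[r]) { s1 <- s1 - X[r, ]; q1 <- q1 - X[r, ]^2; n1 <- n1 - 1L }
        else          { s0 <- s0 - X[r, ]; q0 <- q0 - X[r, ]^2; n0 <- n0 - 1L }
      }
      if (n1 < 2L || n0 < 2L) {
        maj <- if (n1 > n0) "ASD" else "NC"
        C[a, b] <- (maj == "ASD") == isPos[a]
        C[b, a] <- (maj == "ASD") == isPos[b]
        next
      }
      m1 <- s1 / n1; m0 <- s0 / n0
      v1 <- (q1 - n1 * m1^2) / (n1 - 1)
      v0 <- (q0 - n0 * m0^2) / (n0 - 1)
      se <- sqrt((((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)) *
                   (1 / n1 + 1 / n0))
      p <- 2 * stats::pt(-abs((m1 - m0) / se), df = n1 + n0 - 2)
      mask <- se > 0 & !is.na(p) & p < pThreshold
      train <- setdiff(seq_len(N), c(a, b))
      if (!any(mask)) {
        maj <- .majorityClass(ifelse(isPos[train], "ASD", "NC"))
        C[a, b] <- (maj == "ASD") == isPos[a]
        C[b, a] <- (maj == "ASD") == isPos[b]
        next
      }
      yTr <- factor(ifelse(isPos[train], "ASD", "NC"),
                    levels = c("NC", "ASD"))
      fit <- e1071::svm(X[train, mask, drop = FALSE], yTr,
                        kernel = "linear", cost = 1, scale = FALSE,
                        fitted = FALSE)
      pred <- stats::predict(fit, X[c(a, b), mask, drop = FALSE])
      C[a, b] <- (as.character(pred[1]) == "ASD") == isPos[a]
      C[b, a] <- (as.character(pred[2]) == "ASD") == isPos[b]
    }
  }
  C
}

# Per-fold parameter selection from precomputed pairwise-correctness
# matrices: identical in result to calling innerParameterSelection() on the
# fold's training subjects.
.selectFromPairwise <- function(corrList, fold, N, grid) {
  train <- setdiff(seq_len(N), fold)
  winners <- integer(length(train))
  anyDistinction <- FALSE
  for (k in seq_along(train)) {
    i <- train[k]
    acc <- vapply(seq_along(grid), function(g)
      as.numeric(corrList[[g]][i, fold]), numeric(1))
    if (length(unique(acc)) > 1L) anyDistinction <- TRUE
    winners[k] <- which.max(acc)
  }
  freq <- tabulate(winners, nbins = length(grid))
  chosen <- if (!anyDistinction) 1L else which.max(freq)
  out <- grid[chosen]
  attr(out, "index") <- chosen
  attr(out, "frequency") <- freq
  out
}

# Fused feature matrix for all subjects at a fixed per-estimator parameter
# tuple.  Fusion is label-free; results are cached in `cacheEnv` keyed by
# the tuple.
.fusedFeatures <- function(tsList, viewFeatures, params, estimators,
                           fusion, normalizeSlices, cacheEnv) {
  key <- paste(estimators, signif(unlist(params[estimators]), 12),
               sep = "=", collapse = ";")
  if (!is.null(cacheEnv[[key]])) return(cacheEnv[[key]])
  n <- nROIs(tsList[[1]])
  labs <- roiLabels(tsList[[1]])
  N <- length(tsList)
  X <- matrix(0, N, n * (n - 1L) / 2L)
  for (s in seq_len(N)) {
    views <- lapply(estimators, function(est) {
      idx <- attr(params[[est]], "index")
      v <- viewFeatures[[est]][[idx]][s, ]
      ConnectivityMatrix(.matFromUpper(v, n, labs), method = est,
                         sparsityParam = as.numeric(params[[est]]))
    })
    tensor <- stackTensor(views, normalize = normalizeSlices,
                          onZeroSlice = "keep")
    emb <- rescalALS(tensor, fusion)
    X[s, ] <- vectorizeUpper(reconstructFusedFBN(emb))
  }
  cacheEnv[[key]] <- X
  X
}

#' Nested leave-one-out evaluation of the fusion pipeline
#'
#' Implements the full classification protocol. For every outer fold (one
#' held-out subject): (1) each estimator's sparsity parameter is chosen by
#' the frequency-based inner leave-one-out loop ([innerParameterSelection()])
#' run on the training subjects only; (2) per-subject fused networks are
#' built at the selected parameters (fusion is label-free, so fused
#' matrices are cached across folds); (3) t-test feature selection is
#' fitted on the training features only; (4) a linear SVM predicts the
#' held-out subject. Folds whose training selection yields zero features
#' fall back to the training-majority class and are logged. All fold
#' predictions are aggregated into one [MetricsReport-class].
#'
#' Inner cycles are evaluated through a leave-two-out correctness table
#' (fold o's inner cycle i and fold i's inner cycle o share their training
#' set), which halves the classifier fits without changing any result.
#'
#' @param tsList list of [ROITimeSeries-class] objects.
#' @param labels class labels (`"ASD"` / `"NC"`) aligned with `tsList`.
#' @param estimators character subset of `c("PC","SR","MI","CC")`, in slice
#'   order.
#' @param grids named list of per-estimator parameter grids
#'   (see [defaultGrids()]).
#' @param pThreshold t-test selection threshold.
#' @param fusion a [FusionConfig-class]; its rank must not exceed the ROI
#'   count.
#' @param normalizeSlices rescale slices to unit Frobenius norm before
#'   stacking.
#' @param includeSingleViews also evaluate each single-view network (at its
#'   per-fold selected parameter) with the same protocol, as degenerate
#'   baselines.
#' @param verbose emit progress messages.
#' @return List with elements `fused` (a [MetricsReport-class] whose
#'   `foldLog` records, per fold, the held-out subject, selected parameters,
#'   feature count, selected feature indices, prediction and score) and,
#'   when requested, `singleViews` (named list of [MetricsReport-class]).
#' @export
loocvEvaluate <- function(tsList, labels,
                          estimators = c("PC", "SR", "MI", "CC"),
                          grids = defaultGrids(), pThreshold = 0.001,
                          fusion = FusionConfig(),
                          normalizeSlices = TRUE,
                          includeSingleViews = FALSE, verbose = FALSE) {
  y <- .normalizeLabels(labels)
  N <- length(tsList)
  stopifnot(N >= 4L, length(y) == N)
  if (nlevels(droplevels(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  estimators <- match.arg(estimators, c("PC", "SR", "MI", "CC"),
                          several.ok = TRUE)
  viewFeatures <- .precomputeViewFeatures(tsList, estimators, grids, verbose)
  if (verbose) message("building leave-two-out correctness tables")
  pairCorrect <- lapply(estimators, function(est)
    lapply(viewFeatures[[est]], .pairwiseCorrect, y = y,
           pThreshold = pThreshold))
  names(pairCorrect) <- estimators
  cacheEnv <- new.env(parent = emptyenv())
  subjects <- vapply(tsList, subjectID, character(1))

  predF <- factor(rep(NA_character_, N), levels = c("NC", "ASD"))
  scoreF <- numeric(N)
  predSV <- lapply(estimators, function(e)
    factor(rep(NA_character_, N), levels = c("NC", "ASD")))
  names(predSV) <- estimators
  scoreSV <- lapply(estimators, function(e) numeric(N))
  names(scoreSV) <- estimators
  logRows <- vector("list", N)

  for (o in seq_len(N)) {
    train <- setdiff(seq_len(N), o)
    params <- lapply(estimators, function(est)
      .selectFromPairwise(pairCorrect[[est]], o, N, grids[[est]]))
    names(params) <- estimators
    Xfused <- .fusedFeatures(tsList, viewFeatures, params, estimators,
                             fusion, normalizeSlices, cacheEnv)
    pr <- .foldPredict(Xfused, y, train, o, pThreshold)
    predF[o] <- pr$labels
    scoreF[o] <- pr$scores
    if (includeSingleViews) {
      for (est in estimators) {
        Xv <- viewFeatures[[est]][[attr(params[[est]], "index")]]
        pv <- .foldPredict(Xv, y, train, o, pThreshold)
        predSV[[est]][o] <- pv$labels
        scoreSV[[est]][o] <- pv$scores
      }
    }
    logRows[[o]] <- data.frame(
      subject = subjects[o],
      trueLabel = as.character(y[o]),
      predicted = as.character(pr$labels),
      score = pr$scores,
      nFeatures = sum(pr$mask),
      featureIdx = paste(which(pr$mask), collapse = ","),
      zeroFeatureFallback = pr$fallback,
      t(setNames(vapply(estimators, function(e) as.numeric(params[[e]]),
                        numeric(1)), paste0("param", estimators))),
      stringsAsFactors = FALSE)
    if (verbose) message("fold ", o, "/", N, ": ", subjects[o], " -> ",
                         as.character(pr$labels))
  }
  foldLog <- do.call(rbind, logRows)
  out <- list(fused = computeMetrics(y, predF, scoreF, foldLog = foldLog))
  if (includeSingleViews) {
    out$singleViews <- lapply(estimators, function(est)
      computeMetrics(y, predSV[[est]], scoreSV[[est]]))
    names(out$singleViews) <- estimators
  }
  out
}
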