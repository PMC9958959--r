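# Classification protocol building blocks: feature vectorization, pooled
# two-sample t-test selection, linear SVM, metrics, interclass distance.

# Normalize labels to a factor with levels c("NC", "ASD"); ASD = positive
# class (patients), NC = negative (controls). Case-insensitive.
.normalizeLabels <- function(labels) {
  lab <- toupper(trimws(as.character(labels)))
  bad <- setdiff(unique(lab), c("ASD", "NC"))
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (expected ASD or NC)", call. = FALSE)
  factor(lab, levels = c("NC", "ASD"))
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Extracts the n(n-1)/2 upper-triangle edge weights in row-major (i < j)
#' order: (1,2), (1,3), ..., (1,n), (2,3), ... For the 116-ROI AAL
#' parcellation this yields 6670 features per subject.
#'
#' @param W a [ConnectivityMatrix-class] or symmetric numeric matrix.
#' @return Named numeric vector; names are `"<ROIi>|<ROIj>"` label pairs.
#' @examples
#' length(vectorizeUpper(diag(0, 116)))  # 6670
#' @export
vectorizeUpper <- function(W) {
  M <- if (is(W, "ConnectivityMatrix")) W@weights else as.matrix(W)
  if (!.isSymmetric(M)) stop("W must be symmetric", call. = FALSE)
  n <- ncol(M)
  pairs <- .upperPairs(n)
  v <- M[pairs]
  labs <- colnames(M)
  if (!is.null(labs))
    names(v) <- paste(labs[pairs[, 1]], labs[pairs[, 2]], sep = "|")
  v
}

# Vectorized pooled-variance two-sample t-test p-values per feature column.
# Returns NA where the pooled standard error is zero.
.pooledTTestP <- function(X, isPos) {
  n1 <- sum(isPos); n2 <- sum(!isPos)
  stopifnot(n1 >= 2L, n2 >= 2L)
  X1 <- X[isPos, , drop = FALSE]
  X2 <- X[!isPos, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- (colSums(X1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(X2^2) - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df = n1 + n2 - 2)
  p[se <= 0] <- NA_real_
  p
}

#' Two-sample t-test feature selection
#'
#' Marks features whose two-sided pooled-variance two-sample t-test p-value
#' (patients vs. controls) falls strictly below `pThreshold`. Features with
#' zero variance in both classes are never selected.
#'
#' @param X numeric subjects x features matrix.
#' @param labels class labels (`"ASD"` / `"NC"`, case-insensitive), one per
#'   row of `X`.
#' @param pThreshold significance threshold in (0, 1).
#' @param welch use the Welch (unequal-variance) statistic instead of the
#'   pooled default.
#' @return Logical selection mask of length `ncol(X)`, with the p-values as
#'   attribute `"p"`.
#' @export
ttestSelect <- function(X, labels, pThreshold, welch = FALSE) {
  stopifnot(is.matrix(X), pThreshold > 0, pThreshold < 1)
  y <- .normalizeLabels(labels)
  if (nlevels(droplevels(y)) < 2L)
    stop("both classes must be present for t-test selection", call. = FALSE)
  if (min(table(y)) < 2L)
    stop("need at least 2 subjects per class", call. = FALSE)
  isPos <- y == "ASD"
  if (welch) {
    p <- apply(X, 2, function(col) {
      if (stats::sd(col[isPos]) == 0 && stats::sd(col[!isPos]) == 0)
        return(NA_real_)
      stats::t.test(col[isPos], col[!isPos])$p.value
    })
  } else {
    p <- .pooledTTestP(X, isPos)
  }
  mask <- !is.na(p) & p < pThreshold
  attr(mask, "p") <- p
  mask
}

#' Linear support-vector-machine train/predict
#'
#' Soft-margin linear SVM with the cost parameter fixed at its default
#' (C = 1), the classifier used throughout the evaluation protocol. Returns
#' predicted labels and signed decision scores oriented so that positive
#' values favour the patient (ASD) class.
#'
#' @param XTrain,XTest numeric feature matrices (subjects x features).
#' @param yTrain training labels (`"ASD"` / `"NC"`).
#' @return List with `labels` (factor, levels NC/ASD) and `scores` (numeric
#'   decision values for `XTest`).
#' @export
fitPredictLinearSVM <- function(XTrain, yTrain, XTest) {
  y <- .normalizeLabels(yTrain)
  if (nlevels(droplevels(y)) < 2L)
    stop("training fold contains a single class", call. = FALSE)
  XTrain <- as.matrix(XTrain)
  XTest <- as.matrix(XTest)
  fit <- e1071::svm(XTrain, y, kernel = "linear", cost = 1, scale = FALSE)
  pred <- stats::predict(fit, XTest, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  score <- dv[, 1L]
  # orient: libsvm reports the decision value for <first>/<second> level
  firstLevel <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1]][1]
  if (firstLevel != "ASD") score <- -score
  list(labels = factor(as.character(pred), levels = c("NC", "ASD")),
       scores = as.numeric(score))
}

# Mann-Whitney AUC with midrank tie handling.
.rankAUC <- function(scores, isPos) {
  np <- sum(isPos); nn <- sum(!isPos)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[isPos]) - np * (np + 1) / 2) / (np * nn)
}

#' Classification metrics from predictions
#'
#' Builds the confusion counts (positive class = patient/ASD) and the seven
#' evaluation metrics: ACC = (TP+TN)/N, SEN = TP/(TP+FN), SPE = TN/(TN+FP),
#' BAC = (SEN+SPE)/2, PPV = TP/(TP+FP), NPV = TN/(TN+FN), and AUC by the
#' rank (Mann-Whitney) statistic over the decision scores with midranks for
#' ties. Undefined ratios are reported as NaN and flagged, never silently
#' zeroed.
#'
#' @param yTrue,yPred true and predicted labels (`"ASD"` / `"NC"`).
#' @param scores numeric decision scores aligned with `yTrue` (higher =
#'   more ASD-like); used only for the AUC.
#' @param foldLog optional data.frame of per-fold bookkeeping to attach.
#' @return A [MetricsReport-class].
#' @examples
#' rep <- computeMetrics(c("ASD", "ASD", "NC", "NC"),
#'                       c("ASD", "NC", "NC", "NC"),
#'                       scores = c(2, -0.5, -1, -2))
#' metrics(rep)
#' @export
computeMetrics <- function(yTrue, yPred, scores, foldLog = NULL) {
  yt <- .normalizeLabels(yTrue)
  yp <- .normalizeLabels(yPred)
  stopifnot(length(yt) == length(yp), length(scores) == length(yt))
  if (nlevels(droplevels(yt)) < 2L)
    stop("yTrue must contain both classes", call. = FALSE)
  isPos <- yt == "ASD"
  TP <- sum(isPos & yp == "ASD")
  FN <- sum(isPos & yp == "NC")
  TN <- sum(!isPos & yp == "NC")
  FP <- sum(!isPos & yp == "ASD")
  ratio <- function(num, den) if (den == 0) NaN else num / den
  SEN <- ratio(TP, TP + FN)
  SPE <- ratio(TN, TN + FP)
  m <- c(ACC = (TP + TN) / length(yt),
         SEN = SEN, SPE = SPE, BAC = (SEN + SPE) / 2,
         PPV = ratio(TP, TP + FP), NPV = ratio(TN, TN + FN),
         AUC = .rankAUC(scores, isPos))
  undef <- names(m)[is.nan(m)]
  new("MetricsReport", TP = as.integer(TP), TN = as.integer(TN),
      FP = as.integer(FP), FN = as.integer(FN), metrics = m,
      undefined = undef,
      foldLog = if (is.null(foldLog)) data.frame() else foldLog)
}

#' Interclass distance between class-mean networks
#'
#' Separability diagnostic: vectorizes the upper triangle of every subject's
#' network, averages the vectors within each class, and returns the
#' Euclidean distance between the two class representatives. Larger is
#' better; fusion schemes that cancel signed edges shrink it.
#'
#' @param fbns list of [ConnectivityMatrix-class] objects, one per subject.
#' @param labels class labels aligned with `fbns`.
#' @return Single nonnegative number.
#' @export
interclassDistance <- function(fbns, labels) {
  y <- .normalizeLabels(labels)
  stopifnot(length(fbns) == length(y))
  if (any(table(y) == 0L))
    stop("both classes must have at least one member", call. = FALSE)
  V <- t(vapply(fbns, vectorizeUpper, numeric(nROIs(fbns[[1]]) *
                                              (nROIs(fbns[[1]]) - 1) / 2)))
  mPos <- colMeans(V[y == "ASD", , drop = FALSE])
  mNeg <- colMeans(V[y == "NC", , drop = FALSE])
  sqrt(sum((mPos - mNeg)^2))
}
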