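# Seed-deterministic generators: a two-class BOLD-like cohort with a planted
# covariance effect, and exactly low-rank symmetric-slice tensors.

#' Synthetic cohort specification
#'
#' Describes a two-class cohort of multivariate ROI time series. Both
#' classes share a modular (block) correlation structure; the patient class
#' additionally has `effectDelta` added to the correlations of
#' `effectEdges`. Defaults are the package's desk-scale study conditions:
#' 20 subjects per class, 30 ROIs, 150 timepoints, 20 planted edges with a
#' +0.4 correlation shift, AR(1) temporal autocorrelation 0.3.
#'
#' @param nPerClass subjects per class.
#' @param nROIs number of ROIs.
#' @param nTimepoints timepoints per subject (>= 3).
#' @param nEffectEdges number of planted edges drawn at random when
#'   `effectEdges` is NULL.
#' @param effectEdges optional 2-column integer matrix of ROI pairs (i < j).
#' @param effectDelta correlation shift added on planted edges in patients.
#' @param arCoeff AR(1) temporal autocorrelation in [0, 1).
#' @param seed integer seed; all draws are deterministic given it.
#' @return A list of class `"SyntheticCohortSpec"`.
#' @export
SyntheticCohortSpec <- function(nPerClass = 20L, nROIs = 30L,
                                nTimepoints = 150L, nEffectEdges = 20L,
                                effectEdges = NULL, effectDelta = 0.4,
                                arCoeff = 0.3, seed = 1L) {
  stopifnot(nPerClass >= 1L, nROIs >= 2L, nTimepoints >= 3L,
            arCoeff >= 0, arCoeff < 1)
  structure(list(nPerClass = as.integer(nPerClass),
                 nROIs = as.integer(nROIs),
                 nTimepoints = as.integer(nTimepoints),
                 nEffectEdges = as.integer(nEffectEdges),
                 effectEdges = effectEdges,
                 effectDelta = as.numeric(effectDelta),
                 arCoeff = as.numeric(arCoeff), seed = as.integer(seed)),
            class = "SyntheticCohortSpec")
}

#' Synthetic tensor specification
#'
#' Describes an exactly low-rank multiview tensor
#' \eqn{A^{(k)} = P_0 R_0^{(k)} P_0^\top + \text{noise}} with a shared
#' orthonormal factor and symmetric cores — the generative form the joint
#' embedding assumes.
#'
#' @param n slice order (number of nodes).
#' @param rank ground-truth rank r0 (<= n).
#' @param m number of slices.
#' @param noiseSd standard deviation of the symmetric Gaussian noise.
#' @param seed integer seed.
#' @return A list of class `"SyntheticTensorSpec"`.
#' @export
SyntheticTensorSpec <- function(n = 30L, rank = 5L, m = 4L, noiseSd = 0,
                                seed = 1L) {
  stopifnot(rank <= n, noiseSd >= 0, m >= 1L)
  structure(list(n = as.integer(n), rank = as.integer(rank),
                 m = as.integer(m), noiseSd = as.numeric(noiseSd),
                 seed = as.integer(seed)),
            class = "SyntheticTensorSpec")
}

# modular base correlation: consecutive blocks of ~10 ROIs with elevated
# within-block correlation
.baseCorrelation <- function(n, within = 0.35, between = 0.05,
                             blockSize = 10L) {
  C <- matrix(between, n, n)
  starts <- seq(1L, n, by = blockSize)
  for (s in starts) {
    idx <- s:min(s + blockSize - 1L, n)
    C[idx, idx] <- within
  }
  diag(C) <- 1
  C
}

# nearest-PD projection by eigenvalue clipping at 1e-6, re-symmetrization,
# and rescaling back to unit diagonal
.projectPD <- function(C) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 1e-6)
  C2 <- e$vectors %*% (vals * t(e$vectors))
  C2 <- (C2 + t(C2)) / 2
  stats::cov2cor(C2)
}

#' Simulate a two-class BOLD-like cohort
#'
#' Builds the class correlation matrices (shared modular base; patients get
#' `effectDelta` added on the planted edges), projects both to the nearest
#' positive-definite correlation matrix (eigenvalue clipping at 1e-6,
#' re-symmetrization, unit-diagonal rescaling), and draws per-subject
#' multivariate normal series filtered through a stationary AR(1) process so
#' the cross-sectional correlation of each series equals its class matrix.
#'
#' @param spec a [SyntheticCohortSpec()].
#' @return List with `timeSeries` (list of [ROITimeSeries-class], patients
#'   first), `labels` (factor, `"ASD"` for patients / `"NC"` controls),
#'   `covariances` (list with the two ground-truth correlation matrices)
#'   and `effectEdges` (the planted pairs).
#' @examples
#' cohort <- simulateBoldCohort(SyntheticCohortSpec(nPerClass = 2,
#'   nROIs = 10, nTimepoints = 60, nEffectEdges = 5, seed = 3))
#' table(cohort$labels)
#' @export
simulateBoldCohort <- function(spec = SyntheticCohortSpec()) {
  stopifnot(inherits(spec, "SyntheticCohortSpec"))
  .withSeed(spec$seed, {
    n <- spec$nROIs
    base <- .baseCorrelation(n)
    edges <- spec$effectEdges
    if (is.null(edges)) {
      allPairs <- .upperPairs(n)
      pick <- sample(nrow(allPairs), spec$nEffectEdges)
      edges <- allPairs[pick, , drop = FALSE]
    }
    edges <- as.matrix(edges)
    shifted <- base
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1L]; j <- edges[k, 2L]
      shifted[i, j] <- shifted[j, i] <-
        min(max(shifted[i, j] + spec$effectDelta, -0.95), 0.95)
    }
    Cneg <- .projectPD(base)
    Cpos <- .projectPD(shifted)
    for (C in list(Cneg, Cpos)) {
      ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
      if (ev <= 1e-8)
        stop("class covariance not positive definite after projection; ",
             "smallest eigenvalue ", signif(ev, 4), call. = FALSE)
    }
    phi <- spec$arCoeff
    drawSubject <- function(C, id) {
      L <- chol(C)
      v <- spec$nTimepoints
      innov <- matrix(rnorm(v * n), v, n) %*% L
      X <- matrix(0, v, n)
      X[1, ] <- innov[1, ]
      if (v > 1) {
        s <- sqrt(1 - phi^2)
        for (t in 2:v) X[t, ] <- phi * X[t - 1, ] + s * innov[t, ]
      }
      ROITimeSeries(X, subjectID = id,
                    roiLabels = paste0("ROI", seq_len(n)))
    }
    ids <- sprintf("sub%03d", seq_len(2L * spec$nPerClass))
    tsList <- c(
      lapply(seq_len(spec$nPerClass),
             function(s) drawSubject(Cpos, ids[s])),
      lapply(seq_len(spec$nPerClass),
             function(s) drawSubject(Cneg, ids[spec$nPerClass + s])))
    labels <- factor(rep(c("ASD", "NC"), each = spec$nPerClass),
                     levels = c("NC", "ASD"))
    list(timeSeries = tsList, labels = labels,
         covariances = list(ASD = Cpos, NC = Cneg), effectEdges = edges)
  })
}

#' Simulate an exactly low-rank multiview tensor
#'
#' Draws a uniformly random orthonormal \eqn{n \times r_0} factor
#' \eqn{P_0} and symmetric cores \eqn{R_0^{(k)}}, and forms slices
#' \eqn{A^{(k)} = P_0 R_0^{(k)} P_0^\top} plus symmetric Gaussian noise of
#' standard deviation `noiseSd`. With `zeroDiagonal = FALSE` (default) the
#' noiseless slices are exactly rank \eqn{r_0}, the regime in which the
#' factorization recovers \eqn{\mathrm{span}(P_0)} to machine precision;
#' `zeroDiagonal = TRUE` instead applies the pipeline's zero-diagonal
#' convention (which makes the slices full-rank, so exact recovery no
#' longer applies).
#'
#' @param spec a [SyntheticTensorSpec()].
#' @param zeroDiagonal zero the slice diagonals.
#' @return List with `tensor` ([ConnectivityTensor-class]), `P0` (n x r0
#'   orthonormal) and `R0` (list of symmetric r0 x r0 cores).
#' @export
simulateTensor <- function(spec = SyntheticTensorSpec(),
                           zeroDiagonal = FALSE) {
  stopifnot(inherits(spec, "SyntheticTensorSpec"))
  .withSeed(spec$seed, {
    n <- spec$n; r <- spec$rank; m <- spec$m
    P0 <- qr.Q(qr(matrix(rnorm(n * r), n, r)))[, seq_len(r), drop = FALSE]
    P0 <- .signFixColumns(P0)
    R0 <- lapply(seq_len(m), function(k) {
      B <- matrix(rnorm(r * r), r, r)
      (B + t(B)) / 2
    })
    A <- array(0, dim = c(n, n, m))
    for (k in seq_len(m)) {
      S <- P0 %*% R0[[k]] %*% t(P0)
      if (spec$noiseSd > 0) {
        E <- matrix(rnorm(n * n, sd = spec$noiseSd), n, n)
        S <- S + (E + t(E)) / 2
      }
      S <- (S + t(S)) / 2
      if (zeroDiagonal) diag(S) <- 0
      A[, , k] <- S
    }
    tensor <- new("ConnectivityTensor", data = A,
                  roiLabels = paste0("ROI", seq_len(n)),
                  methods = paste0("view", seq_len(m)),
                  normalized = FALSE)
    list(tensor = tensor, P0 = P0, R0 = R0)
  })
}
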