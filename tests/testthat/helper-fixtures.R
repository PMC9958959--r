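# Shared fixtures, all generated in code under fixed seeds.

makeTS <- function(v = 50, n = 5, seed = 1, subjectID = "sub") {
  set.seed(seed)
  ROITimeSeries(matrix(rnorm(v * n), v, n), subjectID = subjectID)
}

randomSymmetricCM <- function(n = 6, seed = 1, method = "PC") {
  set.seed(seed)
  M <- matrix(rnorm(n * n), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  ConnectivityMatrix(M, method = method)
}

# standardized columns as the estimators see them
standardize <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  sweep(Xc, 2, sqrt(colSums(Xc^2)), "/")
}

# small deterministic cohort for protocol tests
smallCohort <- function(nPerClass = 5, nROIs = 12, v = 80, edges = 8,
                        delta = 0.6, seed = 7) {
  simulateBoldCohort(SyntheticCohortSpec(
    nPerClass = nPerClass, nROIs = nROIs, nTimepoints = v,
    nEffectEdges = edges, effectDelta = delta, seed = seed))
}

smallGrids <- function() list(PC = c(0, 0.3, 0.6), SR = c(0.25, 1),
                              MI = c(0, 0.5), CC = c(0, 0.5))
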