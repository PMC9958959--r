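# Inner frequency-based parameter selection and the nested LOOCV protocol.

test_that("a singleton grid is returned unchanged", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4)
  y <- rep(c("ASD", "NC"), each = 5)
  chosen <- suppressWarnings(
    innerParameterSelection(function(g) X, y, grid = 0.7,
                            pThreshold = 0.5))
  expect_equal(as.numeric(chosen), 0.7)
  expect_equal(attr(chosen, "index"), 1L)
})

test_that("a dominant parameter is chosen in every inner cycle", {
  set.seed(2)
  N <- 10
  y <- rep(c("ASD", "NC"), each = N / 2)
  signal <- ifelse(y == "ASD", 2, -2) + rnorm(N, sd = 0.05)
  provider <- function(g) {
    if (g == 1) cbind(f = signal)            # separates perfectly
    else cbind(f = rnorm(N))                 # pure noise
  }
  chosen <- innerParameterSelection(provider, y, grid = c(1, 2),
                                    pThreshold = 0.9)
  expect_equal(as.numeric(chosen), 1)
  expect_equal(attr(chosen, "frequency")[1], N)
})

test_that("the modal winner matches an independently composed inner loop", {
  # oracle: re-run the inner LOO with the exported primitives only
  innerOracle <- function(Xs, y, pThr) {
    N <- length(y)
    winners <- integer(N)
    for (i in seq_len(N)) {
      train <- setdiff(seq_len(N), i)
      acc <- vapply(seq_along(Xs), function(g) {
        mask <- ttestSelect(Xs[[g]][train, , drop = FALSE], y[train], pThr)
        if (!any(mask)) {
          tab <- table(factor(y[train], levels = c("NC", "ASD")))
          maj <- if (tab[["ASD"]] > tab[["NC"]]) "ASD" else "NC"
          return(as.numeric(maj == y[i]))
        }
        fit <- fitPredictLinearSVM(Xs[[g]][train, mask, drop = FALSE],
                                   y[train],
                                   Xs[[g]][i, mask, drop = FALSE])
        as.numeric(as.character(fit$labels) == y[i])
      }, numeric(1))
      winners[i] <- which.max(acc)
    }
    freq <- tabulate(winners, nbins = length(Xs))
    which.max(freq)
  }
  for (seed in 1:4) {
    set.seed(seed)
    N <- 12
    y <- rep(c("ASD", "NC"), each = N / 2)
    base <- ifelse(y == "ASD", 1, -1)
    Xs <- lapply(1:3, function(g)
      cbind(f1 = base * g / 3 + rnorm(N, sd = 1.2),
            f2 = rnorm(N)))
    chosen <- suppressWarnings(
      innerParameterSelection(function(g) Xs[[g]], y, grid = 1:3,
                              pThreshold = 0.5))
    expect_equal(attr(chosen, "index"), innerOracle(Xs, y, 0.5))
  }
})

test_that("the leave-two-out shortcut reproduces the naive inner loop", {
  cohort <- smallCohort(nPerClass = 5, nROIs = 10, v = 60, edges = 6,
                        seed = 31)
  grids <- smallGrids()
  res <- suppressWarnings(loocvEvaluate(
    cohort$timeSeries, cohort$labels, grids = grids, pThreshold = 0.05,
    fusion = FusionConfig(alpha = 0.01, rank = 4, seed = 31)))
  log <- foldLog(res$fused)
  vf <- lapply(c(PC = "PC", SR = "SR", MI = "MI", CC = "CC"), function(est)
    lapply(grids[[est]], function(g) t(vapply(cohort$timeSeries,
      function(ts) {
        fbn <- switch(est, PC = pearsonFBN(ts),
                      SR = sparseRepresentationFBN(ts, g),
                      MI = mutualInformationFBN(ts),
                      CC = correlationsCorrelationFBN(ts))
        if (est != "SR" && g > 0) fbn <- proportionalThreshold(fbn, g)
        vectorizeUpper(fbn)
      }, numeric(45)))))
  for (o in c(1L, 4L, 8L)) {
    train <- setdiff(1:10, o)
    for (est in c("PC", "SR", "MI", "CC")) {
      naive <- suppressWarnings(innerParameterSelection(
        function(g) vf[[est]][[match(g, grids[[est]])]][train, ,
                                                        drop = FALSE],
        cohort$labels[train], grids[[est]], 0.05))
      expect_equal(as.numeric(naive), log[[paste0("param", est)]][o])
    }
  }
})

test_that("nested LOOCV logs one entry per fold with its selections", {
  cohort <- smallCohort(nPerClass = 4, nROIs = 10, v = 60, edges = 6,
                        seed = 5)
  res <- suppressWarnings(loocvEvaluate(
    cohort$timeSeries, cohort$labels, grids = smallGrids(),
    pThreshold = 0.05,
    fusion = FusionConfig(alpha = 0.01, rank = 4, seed = 5)))
  log <- foldLog(res$fused)
  expect_equal(nrow(log), 8L)
  expect_setequal(log$subject,
                  vapply(cohort$timeSeries, subjectID, character(1)))
  expect_true(all(c("paramPC", "paramSR", "paramMI", "paramCC",
                    "nFeatures", "predicted", "score") %in% names(log)))
  expect_true(all(log$paramPC %in% smallGrids()$PC))
  expect_true(all(log$paramSR %in% smallGrids()$SR))
})

test_that("fixed-seed reruns of the protocol are bit-identical", {
  cohort <- smallCohort(nPerClass = 3, nROIs = 8, v = 50, edges = 4,
                        seed = 11)
  run <- function() suppressWarnings(loocvEvaluate(
    cohort$timeSeries, cohort$labels,
    grids = list(PC = c(0, 0.5), SR = 1, MI = 0, CC = 0),
    pThreshold = 0.05,
    fusion = FusionConfig(alpha = 0.01, rank = 3, seed = 9)))
  r1 <- run(); r2 <- run()
  expect_identical(metrics(r1$fused), metrics(r2$fused))
  expect_identical(foldLog(r1$fused), foldLog(r2$fused))
})

test_that("held-out subjects cannot leak into selection decisions", {
  cohort <- smallCohort(nPerClass = 4, nROIs = 10, v = 60, edges = 6,
                        seed = 13)
  grids <- list(PC = c(0, 0.5), SR = c(0.5, 2), MI = c(0, 0.5),
                CC = c(0, 0.5))
  run <- function(tsList) suppressWarnings(loocvEvaluate(
    tsList, cohort$labels, grids = grids, pThreshold = 0.05,
    fusion = FusionConfig(alpha = 0.01, rank = 4, seed = 13)))
  base <- foldLog(run(cohort$timeSeries)$fused)
  for (k in c(1L, 6L)) {
    perturbed <- cohort$timeSeries
    set.seed(100 + k)
    perturbed[[k]] <- ROITimeSeries(
      matrix(rnorm(60 * 10), 60, 10), subjectID = subjectID(perturbed[[k]]),
      roiLabels = roiLabels(perturbed[[k]]))
    pl <- foldLog(run(perturbed)$fused)
    # the fold holding out subject k must be unaffected in its selections
    cols <- c("featureIdx", "nFeatures", "paramPC", "paramSR", "paramMI",
              "paramCC")
    expect_identical(pl[k, cols], base[k, cols])
  }
})

test_that("zero-feature folds fall back to the training majority", {
  # null cohort and a near-impossible threshold: nothing is ever selected
  cohort <- simulateBoldCohort(SyntheticCohortSpec(
    nPerClass = 4, nROIs = 8, nTimepoints = 50, nEffectEdges = 4,
    effectDelta = 0, seed = 17))
  res <- suppressWarnings(loocvEvaluate(
    cohort$timeSeries, cohort$labels, estimators = c("PC", "MI", "CC"),
    grids = list(PC = 0, MI = 0, CC = 0), pThreshold = 1e-8,
    fusion = FusionConfig(alpha = 0.01, rank = 3, seed = 17)))
  log <- foldLog(res$fused)
  expect_true(all(log$zeroFeatureFallback))
  # with balanced classes, the training majority is always the other class
  expect_true(all(log$predicted != log$trueLabel))
})
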