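# Single-view estimators: Pearson, sparse representation, mutual
# information, correlation's correlation, and proportional thresholding.

test_that("pearsonFBN reproduces hand-computed correlations", {
  ts <- ROITimeSeries(cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4)))
  expect_equal(weights(pearsonFBN(ts))[1, 2], 0.8)

  # perfect positive linear dependence: all off-diagonal weights 1
  x <- c(0.3, 1.2, -0.5, 2.2, 0.1)
  ts2 <- ROITimeSeries(cbind(a = x, b = 2 * x + 3, c = 0.5 * x - 1))
  W <- weights(pearsonFBN(ts2))
  expect_equal(W[upper.tri(W)], rep(1, 3))

  # perfect anticorrelation
  ts3 <- ROITimeSeries(cbind(a = x, b = -x))
  expect_equal(weights(pearsonFBN(ts3))[1, 2], -1)

  expect_equal(diag(weights(pearsonFBN(ts2))), rep(0, 3),
               ignore_attr = TRUE)
})

test_that("pearsonFBN is invariant to positive affine rescaling of ROIs", {
  for (seed in 1:3) {
    ts <- makeTS(40, 6, seed = seed)
    X <- tsData(ts)
    a <- runif(6, 0.5, 3)
    b <- rnorm(6, sd = 4)
    ts2 <- ROITimeSeries(sweep(sweep(X, 2, a, "*"), 2, b, "+"),
                         roiLabels = roiLabels(ts))
    expect_lt(max(abs(weights(pearsonFBN(ts)) - weights(pearsonFBN(ts2)))),
              1e-10)
  }
})

test_that("constant ROI columns are rejected with the ROI named", {
  X <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(ROITimeSeries(X), "constant.*b")
})

test_that("sparse representation matches an independent lasso solver", {
  skip_if_not_installed("glmnet")
  ts <- makeTS(50, 5, seed = 5)
  X <- standardize(tsData(ts))
  v <- nrow(X)
  for (lam in c(0.25, 1)) {
    Wraw <- srCoefficients(ts, lam)
    for (i in 1:5) {
      idx <- setdiff(1:5, i)
      g <- glmnet::glmnet(X[, idx], X[, i], lambda = lam / (2 * v),
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-14)
      expect_lt(max(abs(as.numeric(stats::coef(g))[-1] - Wraw[idx, i])),
                1e-4)
    }
  }
})

test_that("sparse representation structure: zero diagonal, symmetry, and
           the all-zero solution under a dominating penalty", {
  ts <- makeTS(50, 5, seed = 2)
  W <- weights(sparseRepresentationFBN(ts, 0.25))
  expect_equal(diag(W), rep(0, 5), ignore_attr = TRUE)
  expect_lt(max(abs(W - t(W))), 1e-12)
  # unit-norm columns have |x_j' x_i| <= 1, so lambda = 2^5 zeroes all
  expect_true(all(weights(sparseRepresentationFBN(ts, 2^5)) == 0))
})

test_that("sparse representation sparsity is non-increasing in lambda", {
  ts <- makeTS(60, 8, seed = 3)
  nz <- vapply(2^(-5:5), function(l) sum(srCoefficients(ts, l) != 0),
               numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("mutual information reproduces closed-form histogram values", {
  # perfectly co-binned 2-bin signals: joint counts [[2,0],[0,2]] over v=4
  ts <- ROITimeSeries(cbind(a = c(0.1, 0.2, 0.9, 1.0),
                            b = c(0.15, 0.05, 0.95, 0.85)))
  expect_equal(weights(mutualInformationFBN(ts, nBins = 2))[1, 2], log(2))

  # factorizable joint distribution on the bin grid: MI = 0
  tsInd <- ROITimeSeries(cbind(a = c(0, 0.1, 0.9, 1.0),
                               b = c(0, 0.9, 0.1, 1.0)))
  expect_equal(weights(mutualInformationFBN(tsInd, nBins = 2))[1, 2], 0)

  # identical signals: MI equals the marginal bin entropy
  x <- c(0.0, 0.05, 0.3, 0.5, 0.52, 0.9, 1.0, 0.1)
  tsId <- ROITimeSeries(cbind(a = x, b = x, c = rnorm(8)))
  nBins <- 3L
  xs <- standardize(tsData(tsId))[, 1]
  br <- seq(min(xs), max(xs), length.out = nBins + 1)
  cnt <- tabulate(findInterval(xs, br, rightmost.closed = TRUE,
                               all.inside = TRUE), nBins)
  p <- cnt[cnt > 0] / length(x)
  expect_equal(weights(mutualInformationFBN(tsId, nBins = nBins))[1, 2],
               -sum(p * log(p)))
})

test_that("mutual information networks are symmetric and nonnegative", {
  for (seed in 1:3) {
    W <- weights(mutualInformationFBN(makeTS(80, 6, seed = seed)))
    expect_true(all(W >= 0))
    expect_lt(max(abs(W - t(W))), 1e-12)
    expect_equal(diag(W), rep(0, 6), ignore_attr = TRUE)
  }
})

test_that("correlation's correlation equals the two-step composition", {
  ts <- makeTS(50, 6, seed = 9)
  H <- weights(correlationsCorrelationFBN(ts))
  # brute-force oracle: correlate the columns of the low-order correlation
  # matrix (diagonal kept at 1), then zero the diagonal
  Wlow <- stats::cor(tsData(ts))
  Horacle <- stats::cor(Wlow)
  diag(Horacle) <- 0
  expect_equal(H, Horacle, ignore_attr = TRUE, tolerance = 1e-12)
  expect_lt(max(abs(H - t(H))), 1e-12)
  expect_equal(diag(H), rep(0, 6), ignore_attr = TRUE)
})

test_that("ROIs with identical low-order profiles get high-order weight 1", {
  x <- rnorm(30)
  ts <- ROITimeSeries(cbind(a = x, b = x, c = rnorm(30), d = rnorm(30)))
  expect_equal(weights(correlationsCorrelationFBN(ts))[1, 2], 1)
})

test_that("proportional thresholding removes exactly the weakest edges", {
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[2, 1] <- 0.9
  M[1, 3] <- M[3, 1] <- -0.5
  M[2, 3] <- M[3, 2] <- 0.1
  W <- ConnectivityMatrix(M)
  Wt <- proportionalThreshold(W, 1 / 3)  # floor(1) = 1 edge dropped
  expect_equal(weights(Wt)[2, 3], 0)
  expect_equal(weights(Wt)[1, 2], 0.9)
  expect_equal(weights(Wt)[1, 3], -0.5)  # strong negative edge survives

  # removeProp = 0 is the identity
  expect_equal(weights(proportionalThreshold(W, 0)), weights(W))

  expect_error(proportionalThreshold(W, 1), "removeProp")
  expect_error(proportionalThreshold(W, -0.1), "removeProp")
})

test_that("thresholding keeps the edge count contract and symmetry", {
  for (seed in 1:3) {
    W <- randomSymmetricCM(8, seed = seed)
    E <- 8 * 7 / 2
    for (p in c(0.2, 0.5, 0.99)) {
      Wt <- weights(proportionalThreshold(W, p))
      expect_equal(sum(Wt[upper.tri(Wt)] != 0), E - floor(p * E))
      expect_lt(max(abs(Wt - t(Wt))), 1e-12)
      expect_equal(diag(Wt), rep(0, 8), ignore_attr = TRUE)
    }
  }
})

test_that("composing thresholds equals the single larger removal", {
  for (seed in 4:6) {
    W <- randomSymmetricCM(7, seed = seed)
    a <- proportionalThreshold(proportionalThreshold(W, 0.3), 0.6)
    b <- proportionalThreshold(W, 0.6)
    expect_equal(weights(a), weights(b))
  }
})
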