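# Tensor stacking, ALS updates, factorization recovery, reconstruction,
# eigenvector centrality.

test_that("stackTensor copies, validates and normalizes slices", {
  ts <- makeTS(40, 5, seed = 1)
  pc <- pearsonFBN(ts)
  mi <- mutualInformationFBN(ts)

  # single slice, normalize off: identity
  t1 <- stackTensor(list(pc), normalize = FALSE)
  expect_equal(tensorData(t1)[, , 1], weights(pc), ignore_attr = TRUE)

  # normalize on: unit Frobenius norms
  t2 <- stackTensor(list(pc, mi), normalize = TRUE)
  for (k in 1:2)
    expect_equal(sqrt(sum(tensorData(t2)[, , k]^2)), 1, tolerance = 1e-12)

  # explicit rescale factors on slices with known norms
  M <- matrix(0, 4, 4); M[1, 2] <- M[2, 1] <- sqrt(2)      # norm 2
  N <- matrix(0, 4, 4); N[3, 4] <- N[4, 3] <- sqrt(32)     # norm 8
  t3 <- stackTensor(list(ConnectivityMatrix(M), ConnectivityMatrix(N)))
  expect_equal(tensorData(t3)[1, 2, 1], sqrt(2) / 2)
  expect_equal(tensorData(t3)[3, 4, 2], sqrt(32) / 8)

  # structural errors name the offending slice
  small <- ConnectivityMatrix(matrix(0, 3, 3))
  expect_error(stackTensor(list(pc, small)), "slice 2")
  zero <- ConnectivityMatrix(matrix(0, 5, 5),
                             roiLabels = roiLabels(pc))
  expect_error(stackTensor(list(pc, zero), normalize = TRUE),
               "zero Frobenius norm")
})

test_that("initEmbedding returns leading eigenvectors, sign-fixed", {
  # path graph P3: top eigenvalue sqrt(2), eigenvector (1, sqrt(2), 1)/2
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  P <- initEmbedding(array(A, c(3, 3, 1)), 1)
  expect_equal(as.numeric(P), c(1, sqrt(2), 1) / 2, tolerance = 1e-12)

  # orthonormality and completeness
  arr <- tensorData(simulateTensor(SyntheticTensorSpec(n = 10, rank = 4,
                                                       m = 3, seed = 2))$tensor)
  P4 <- initEmbedding(arr, 4)
  expect_lt(max(abs(crossprod(P4) - diag(4))), 1e-10)
  P10 <- initEmbedding(arr, 10)
  expect_lt(max(abs(tcrossprod(P10) - diag(10))), 1e-10)
})

test_that("updateCore matches its closed forms and the ridge oracle", {
  set.seed(4)
  n <- 6; r <- 3
  A <- matrix(rnorm(n * n), n, n); A <- (A + t(A)) / 2
  arr <- array(A, c(n, n, 1))
  P <- qr.Q(qr(matrix(rnorm(n * r), n, r)))

  # orthonormal P, alpha = 0: R = P'AP exactly
  expect_equal(updateCore(arr, P, 0)[[1]], crossprod(P, A %*% P),
               tolerance = 1e-12)
  # orthonormal P, alpha = 1: R = P'AP / 2
  expect_equal(updateCore(arr, P, 1)[[1]], crossprod(P, A %*% P) / 2,
               tolerance = 1e-12)

  # general P, alpha > 0: matches the dense ridge normal-equation solve of
  # vec(R) in ||A - P R P'||_F^2 + alpha ||R||_F^2
  Pg <- matrix(rnorm(n * r), n, r)
  for (alpha in c(0.1, 2)) {
    R <- updateCore(arr, Pg, alpha)[[1]]
    K <- kronecker(crossprod(Pg), crossprod(Pg)) + alpha * diag(r * r)
    rhs <- as.numeric(crossprod(Pg, A %*% Pg))
    expect_equal(as.numeric(R), solve(K, rhs), tolerance = 1e-8)
  }

  expect_error(updateCore(arr, matrix(0, n, r), 0), "rank deficient")
})

test_that("updateEmbedding has the exact-factorization fixed point", {
  set.seed(8)
  n <- 8; r <- 3
  P <- qr.Q(qr(matrix(rnorm(n * r), n, r)))
  R <- lapply(1:2, function(k) {
    B <- matrix(rnorm(r * r), r, r); (B + t(B)) / 2
  })
  A <- array(0, c(n, n, 2))
  for (k in 1:2) A[, , k] <- P %*% R[[k]] %*% t(P)

  expect_equal(updateEmbedding(A, P, R, 0), P, tolerance = 1e-10)

  # zero cores with alpha > 0: zero numerator
  R0 <- lapply(1:2, function(k) matrix(0, r, r))
  expect_equal(updateEmbedding(A, P, R0, 1), matrix(0, n, r))
  expect_error(updateEmbedding(A, P, R0, 0), "singular")

  # very large alpha drives the update to zero
  expect_lt(max(abs(updateEmbedding(A, P, R, 1e12))), 1e-9)
})

test_that("rescalALS recovers noiseless low-rank tensors exactly", {
  sim <- simulateTensor(SyntheticTensorSpec(n = 20, rank = 4, m = 3,
                                            noiseSd = 0, seed = 13))
  emb <- rescalALS(sim$tensor, FusionConfig(alpha = 0, rank = 4, seed = 13))
  expect_lt(tail(fitTrace(emb), 1), 1e-6)
  expect_lt(max(principalAngles(embeddingFactor(emb), sim$P0)), 1e-3)
  expect_true(all(diff(fitTrace(emb)) <= 1e-9))
})

test_that("rescalALS stopping rule and reproducibility", {
  sim <- simulateTensor(SyntheticTensorSpec(n = 12, rank = 3, m = 2,
                                            noiseSd = 0.05, seed = 3))
  # huge epsilon: exactly one sweep runs
  emb1 <- rescalALS(sim$tensor, FusionConfig(alpha = 0.1, rank = 3,
                                             epsilon = 1e9, seed = 1))
  expect_equal(emb1@iterationsRun, 1L)
  expect_length(fitTrace(emb1), 2L)  # initial fit + one sweep

  # fixed seed is bit-reproducible
  cfg <- FusionConfig(alpha = 0.1, rank = 3, seed = 42)
  e1 <- rescalALS(sim$tensor, cfg)
  e2 <- rescalALS(sim$tensor, cfg)
  expect_identical(embeddingFactor(e1), embeddingFactor(e2))
  expect_identical(fitTrace(e1), fitTrace(e2))

  expect_error(rescalALS(sim$tensor, FusionConfig(rank = 13)), "rank")
})

test_that("reconstruction recovers a noiseless single slice off-diagonal", {
  sim <- simulateTensor(SyntheticTensorSpec(n = 15, rank = 4, m = 1,
                                            noiseSd = 0, seed = 21))
  emb <- rescalALS(sim$tensor, FusionConfig(alpha = 0, rank = 4, seed = 21))
  W <- weights(reconstructFusedFBN(emb, mode = "inner"))
  target <- tensorData(sim$tensor)[, , 1]
  # the embedding spans P0, so P R P' must reproduce the slice; compare the
  # Gram reconstruction against the slice with both diagonals zeroed
  recon <- embeddingFactor(emb) %*% coreSlices(emb)[[1]] %*%
    t(embeddingFactor(emb))
  diag(recon) <- 0; diag(target) <- 0
  expect_lt(max(abs(recon - target)), 1e-6)
  # inner-mode output is a zero-diagonal Gram matrix: PSD up to rounding
  G <- tcrossprod(embeddingFactor(emb))
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
})

test_that("pearson reconstruction respects row affine structure", {
  P <- rbind(c(1, 2, 3), c(2.5, 4.5, 6.5), c(0.3, -1, 2))  # p1 = 2 p2 + c?
  P[1, ] <- 2 * P[3, ] + 5
  emb <- new("JointEmbedding", P = P, R = list(diag(3)),
             fitTrace = c(1, 0.5), iterationsRun = 1L, converged = TRUE,
             config = FusionConfig(rank = 3))
  W <- weights(reconstructFusedFBN(emb, mode = "pearson"))
  expect_equal(W[1, 3], 1)
  # constant row is rejected by name
  P2 <- P; P2[2, ] <- 7
  emb2 <- new("JointEmbedding", P = P2, R = list(diag(3)),
              fitTrace = c(1, 0.5), iterationsRun = 1L, converged = TRUE,
              config = FusionConfig(rank = 3))
  expect_error(reconstructFusedFBN(emb2, mode = "pearson"), "constant")
})

test_that("eigenvector centrality has its closed-form values", {
  # complete graph K_n: uniform scores 1/sqrt(n), eigenvalue n - 1
  n <- 5
  K <- ConnectivityMatrix(matrix(1, n, n) - diag(n))
  cv <- eigenvectorCentrality(K)
  expect_equal(centralityScores(cv), rep(1 / sqrt(n), n), tolerance = 1e-12)
  expect_equal(cv@eigenvalue, n - 1)

  # star K_{1,3}: eigenvalue sqrt(3); centre = sqrt(3) x leaf
  S <- matrix(0, 4, 4); S[1, 2:4] <- S[2:4, 1] <- 1
  cvs <- eigenvectorCentrality(ConnectivityMatrix(S))
  expect_equal(cvs@eigenvalue, sqrt(3), tolerance = 1e-12)
  sc <- centralityScores(cvs)
  expect_equal(sc[1] / sc[2], sqrt(3), tolerance = 1e-10)

  # tied top eigenvalue warns but stays deterministic
  D <- matrix(0, 4, 4); D[1, 2] <- D[2, 1] <- 1; D[3, 4] <- D[4, 3] <- 1
  expect_warning(eigenvectorCentrality(ConnectivityMatrix(D)), "tied")
})

test_that("the joint embedding realizes eigenvector centrality", {
  # single symmetric slice with dominant positive spectrum
  set.seed(6)
  B <- matrix(rnorm(400), 20, 20)
  A <- crossprod(B) / 20 + diag(20)  # PSD with a clear dominant part
  e <- eigen(A, symmetric = TRUE)

  # r = 1 with reorthonormalization: P aligns with the centrality vector
  emb1 <- rescalALS(array(A, c(20, 20, 1)),
                    FusionConfig(alpha = 0, rank = 1, epsilon = 1e-14,
                                 tMax = 500, reorthonormalize = TRUE,
                                 seed = 2))
  p1 <- as.numeric(embeddingFactor(emb1))
  x <- e$vectors[, 1]
  expect_lt(min(sqrt(sum((p1 - x)^2)), sqrt(sum((p1 + x)^2))), 1e-6)

  # r = 3: span(P) equals the top-3 eigenspace
  emb3 <- rescalALS(array(A, c(20, 20, 1)),
                    FusionConfig(alpha = 0, rank = 3, epsilon = 1e-14,
                                 tMax = 500, reorthonormalize = TRUE,
                                 seed = 2))
  expect_lt(max(principalAngles(embeddingFactor(emb3), e$vectors[, 1:3])),
            1e-6)
  expect_true(all(diff(fitTrace(emb3)) <= 1e-9))
})
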