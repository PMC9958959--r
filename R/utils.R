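# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

.isSymmetric <- function(M, tol = 1e-10) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol
}

# Center each column and scale it to unit l2 norm.  This is the shared
# standardization applied before every estimator; Pearson correlation and
# equal-width-bin mutual information are invariant to it, and it makes the
# sparse-representation lambda grid scale-meaningful.
.standardizeColumns <- function(X) {
  Xc <- sweep(X, 2, colMeans(X), "-")
  nrm <- sqrt(colSums(Xc^2))
  if (any(nrm == 0)) {
    bad <- which(nrm == 0)[1]
    lbl <- colnames(X)[bad]
    stop("constant (zero-variance) ROI column: ",
         if (is.null(lbl)) bad else lbl, call. = FALSE)
  }
  sweep(Xc, 2, nrm, "/")
}

# Fix the sign of each column so its largest-magnitude entry is positive
# (first such entry on magnitude ties).
.signFixColumns <- function(M) {
  for (j in seq_len(ncol(M))) {
    i <- which.max(abs(M[, j]))
    if (M[i, j] < 0) M[, j] <- -M[, j]
  }
  M
}

.frobenius <- function(M) sqrt(sum(M^2))

#' Principal angles between two subspaces
#'
#' Computes the principal angles (in radians) between the column spaces of two
#' matrices, via the singular values of the product of their orthonormal
#' bases. Used to verify subspace recovery of the joint embedding.
#'
#' @param A,B numeric matrices with the same number of rows.
#' @return Numeric vector of principal angles in radians, ascending.
#' @examples
#' principalAngles(diag(4)[, 1:2], diag(4)[, 1:2])
#' @export
principalAngles <- function(A, B) {
  Qa <- qr.Q(qr(A))
  Qb <- qr.Q(qr(B))
  s <- svd(crossprod(Qa, Qb))$d
  acos(pmin(pmax(s, -1), 1))
}
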