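# Complete orthogonal decomposition and minimum-norm solves.
#
# The constraint matrices of eNME model systems are rank-deficient (the
# marginal rows of different SNPs share the prevalence row in their span),
# so plain QR back-substitution is not applicable; a rank-revealing
# factorization is required both for the minimum 2-norm solution and for an
# orthonormal null-space basis.  The COD is assembled from two LAPACK QR
# factorizations: a column-pivoted QR of A reveals the numerical rank r and
# leaves A P = Q [R1; 0] with R1 (r x n) of full row rank; a second QR of
# t(R1) then compresses R1 = [T 0] Z' with T (r x r) lower-triangular, giving
#
#   A P = Q [T 0; 0 0] Z' .

#' Complete orthogonal decomposition of a matrix
#'
#' Computes the rank-revealing factorization `A[, pivot] = Q M Z'` where `M`
#' is zero except for an r x r lower-triangular leading block `R11` with
#' nonzero diagonal, and r is the numerical rank (singular values below
#' `max(dim(A)) * eps * largest` treated as zero, via the pivoted-QR
#' diagonal).
#'
#' @param A numeric matrix (m x n), typically wide (m < n).
#' @param tol relative rank tolerance; diagonal entries of the pivoted R
#'   factor smaller than `tol * |R[1,1]|` are treated as zero.  Default
#'   `max(dim(A)) * .Machine$double.eps`.
#' @return a [CODFactorization-class].
#' @examples
#' A <- matrix(rnorm(3 * 8), 3, 8)
#' f <- codFactor(A)
#' f@rank
#' @export
codFactor <- function(A, tol = NULL) {
  stopifnot(is.matrix(A), is.numeric(A))
  m <- nrow(A); n <- ncol(A)
  if (is.null(tol)) tol <- max(m, n) * .Machine$double.eps
  qr1 <- qr(A, LAPACK = TRUE)
  R <- qr.R(qr1)
  d <- abs(diag(R))
  r <- if (length(d) == 0L || d[1L] == 0) 0L else
    sum(d > tol * d[1L])
  Q <- qr.Q(qr1, complete = TRUE)                 # m x m
  if (r == 0L) {
    return(new("CODFactorization",
               Q = Q, Z = diag(n), R11 = matrix(numeric(), 0L, 0L),
               pivot = as.integer(qr1$pivot), rank = 0L))
  }
  R1 <- R[seq_len(r), , drop = FALSE]             # r x n, full row rank
  qr2 <- qr(t(R1))
  Z <- qr.Q(qr2, complete = TRUE)                 # n x n
  Tt <- qr.R(qr2)[seq_len(r), seq_len(r), drop = FALSE]  # upper-tri
  R11 <- t(Tt)                                    # lower-tri, R1 = [R11 0] Z'
  new("CODFactorization",
      Q = Q, Z = Z, R11 = R11,
      pivot = as.integer(qr1$pivot), rank = r)
}

#' Minimum-norm solution of a (possibly rank-deficient) linear system
#'
#' Given the [codFactor()] factorization of `A`, returns the unique minimum
#' 2-norm `x` with `A x = b` (consistent case), or the minimum-norm
#' least-squares solution when `leastSquares = TRUE`.  With
#' `leastSquares = FALSE` (the default) an inconsistent right-hand side —
#' one whose projection outside the column space of `A` exceeds `tol` —
#' raises an error.
#'
#' @param fact a [CODFactorization-class].
#' @param b right-hand side, length `nrow(A)`.
#' @param leastSquares if `TRUE`, ignore the inconsistent component of `b`
#'   and return the least-squares minimum-norm solution.
#' @param tol consistency tolerance on the residual norm. Default 1e-8.
#' @return numeric solution vector of length `ncol(A)`.
#' @examples
#' A <- matrix(c(1, 1), 1, 2)
#' codSolve(codFactor(A), 2)  # c(1, 1): the symmetric minimum-norm solution
#' @export
codSolve <- function(fact, b, leastSquares = FALSE, tol = 1e-8) {
  stopifnot(is(fact, "CODFactorization"))
  m <- nrow(fact@Q); n <- nrow(fact@Z)
  if (length(b) != m) stop("length(b) must equal nrow(A)")
  r <- fact@rank
  if (r == 0L) {
    if (!leastSquares && sqrt(sum(b^2)) > tol)
      stop("system is inconsistent: b is nonzero but A has rank 0")
    return(numeric(n))
  }
  c_ <- drop(crossprod(fact@Q, b))                # Q'b
  if (!leastSquares && m > r) {
    resid <- sqrt(sum(c_[(r + 1L):m]^2))
    if (resid > tol)
      stop(sprintf(
        "system is inconsistent: residual %.3g exceeds tolerance %.3g",
        resid, tol))
  }
  y1 <- forwardsolve(fact@R11, c_[seq_len(r)])
  xp <- drop(fact@Z %*% c(y1, numeric(n - r)))    # solution of (A P) x~ = b
  x <- numeric(n)
  x[fact@pivot] <- xp
  x
}

#' Orthonormal basis of the null space of a factorized matrix
#'
#' Returns an `n x (n - r)` matrix `N` with orthonormal columns spanning
#' null(A): `A N = 0` and `N' N = I`.  When `A` has full column rank the
#' basis is empty (0 columns), which is not an error.
#'
#' @param fact a [CODFactorization-class].
#' @return numeric matrix with `ncol(A)` rows and `ncol(A) - rank` columns.
#' @export
nullSpaceBasis <- function(fact) {
  stopifnot(is(fact, "CODFactorization"))
  n <- nrow(fact@Z); r <- fact@rank
  if (r >= n) return(matrix(numeric(), n, 0L))
  Np <- fact@Z[, (r + 1L):n, drop = FALSE]
  N <- matrix(0, n, n - r)
  N[fact@pivot, ] <- Np
  N
}

# Reconstruct A from its factorization (used by validity tests).
codReconstruct <- function(fact) {
  m <- nrow(fact@Q); n <- nrow(fact@Z); r <- fact@rank
  M <- matrix(0, m, n)
  if (r > 0L) M[seq_len(r), seq_len(r)] <- fact@R11
  AP <- fact@Q %*% M %*% t(fact@Z)
  A <- matrix(0, m, n)
  A[, fact@pivot] <- AP
  A
}

#' @export
setMethod("show", "CODFactorization", function(object) {
  cat(sprintf("CODFactorization: %d x %d, numerical rank %d (null space dim %d)\n",
              nrow(object@Q), nrow(object@Z), object@rank,
              nrow(object@Z) - object@rank))
  invisible(NULL)
})
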