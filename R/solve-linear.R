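# Prevalence-constrained (linear) eNME model solving.
#
# The 3K marginal-penetrance constraints and the prevalence constraint are
# linear in the 3^K unknown penetrance values, giving a wide system
# A x = b with m = 3K+1 << n = 3^K.  The minimum 2-norm solution is unique
# and found through the complete orthogonal decomposition; a non-degenerate
# (heritability > 0) table inside the [0,1] box is then reached by
# hit-and-run sampling along null-space directions, which moves freely on
# the constraint manifold without ever violating A x = b.

#' Build the linear constraint system of a prevalence-only eNME model
#'
#' One row per (SNP k, genotype j) pair plus one prevalence row.  The
#' marginal row for (k, j) puts, on every cell i with digit_k(i) = j, the
#' conditional frequency of that cell given SNP k's genotype
#' (the product of the other SNPs' genotype frequencies), and 0 elsewhere;
#' the prevalence row carries the joint cell frequencies P(g_i).  Every row
#' sums to 1 and every entry of b is the target prevalence, so the table
#' without marginal effects is exactly the solution set of `A x = b`
#' intersected with the \[0,1\] box.
#'
#' @param spec a [ModelSpec-class].
#' @return a [LinearSystem-class] with `3K + 1` rows and `3^K` columns; rows
#'   are named `"snp<k>:<genotype>"` and `"prevalence"`.
#' @export
buildLinearSystem <- function(spec) {
  stopifnot(is(spec, "ModelSpec"))
  K <- spec@K
  n <- 3L^K
  f <- jointFreqsFromMafs(spec@mafs)
  digs <- allCellDigits(K)
  m <- 3L * K + 1L
  A <- matrix(0, m, n)
  rn <- character(m)
  geno <- c("AA", "Aa", "aa")
  row <- 0L
  for (k in seq_len(K)) {
    for (j in 0:2) {
      row <- row + 1L
      sel <- digs[, k] == j
      w <- rep(1, sum(sel))
      for (l in seq_len(K)) if (l != k)
        w <- w * f$perSnp[l, digs[sel, l] + 1L]
      A[row, sel] <- w
      rn[row] <- sprintf("snp%d:%s", k, geno[j + 1L])
    }
  }
  A[m, ] <- f$joint
  rn[m] <- "prevalence"
  rownames(A) <- rn
  new("LinearSystem", A = A, b = rep(spec@prevalence, m), spec = spec)
}

#' Minimum-norm solution of a linear eNME system
#'
#' Factorizes the constraint matrix by complete orthogonal decomposition
#' and returns the unique minimum 2-norm solution together with the
#' factorization (from which the null-space basis is obtained).
#'
#' @param sys a [LinearSystem-class].
#' @param tol consistency tolerance, passed to [codSolve()].
#' @return a list with components `x` (minimum-norm solution) and `factors`
#'   (a [CODFactorization-class]).
#' @export
codMinNormSolve <- function(sys, tol = 1e-8) {
  stopifnot(is(sys, "LinearSystem"))
  fact <- codFactor(sys@A)
  x <- codSolve(fact, sys@b, leastSquares = FALSE, tol = tol)
  list(x = x, factors = fact)
}

#' Sample a feasible, non-degenerate penetrance table
#'
#' Starting from a point on the constraint manifold (the minimum-norm
#' solution if it lies inside the \[0,1\] box, otherwise the constant
#' prevalence table, which is always feasible), performs `mixingSteps`
#' hit-and-run moves: draw a random null-space direction `u = N z` (z
#' standard normal), compute the exact step interval keeping all
#' coordinates in \[0,1\], and jump to a uniform point of that interval.
#' Every iterate satisfies `A x = b` exactly (up to rounding), so the walk
#' explores the solution polytope.  The final point is accepted if its
#' heritability reaches `minHeritability`; otherwise a fresh walk is run,
#' up to `maxAttempts` times.
#'
#' @param xMin minimum-norm solution from [codMinNormSolve()].
#' @param basis orthonormal null-space basis from [nullSpaceBasis()].
#' @param spec the [ModelSpec-class] being solved.
#' @param minHeritability smallest acceptable heritability; tables below it
#'   are effectively null models. Default 1e-3.
#' @param maxAttempts restart budget. Default 1000.
#' @param mixingSteps hit-and-run moves per attempt. Default 20.
#' @return a [SolverResult-class] with `iterations = 0`.
#' @export
sampleFeasibleTable <- function(xMin, basis, spec,
                                minHeritability = 1e-3,
                                maxAttempts = 1000L,
                                mixingSteps = 20L) {
  stopifnot(is(spec, "ModelSpec"))
  n <- 3L^spec@K
  sys <- buildLinearSystem(spec)
  inBox <- function(x) all(x >= 0 & x <= 1)
  start <- if (inBox(xMin)) xMin else rep(spec@prevalence, n)

  finish <- function(x, attempts) {
    x <- pmin(pmax(x, 0), 1)
    tab <- penetranceTable(x, spec@mafs)
    new("SolverResult",
        table = tab,
        residualNorm = sqrt(sum((sys@A %*% x - sys@b)^2)),
        achievedHeritability = heritability(tab),
        attempts = as.integer(attempts),
        iterations = 0L,
        seed = NA_integer_)
  }

  if (ncol(basis) == 0L) {
    if (!inBox(xMin))
      stop("infeasible: the system has a unique solution outside [0, 1]")
    res <- finish(xMin, 1L)
    if (res@achievedHeritability < minHeritability)
      stop(sprintf(
        "infeasible: unique solution has heritability %.3g below the minimum %.3g",
        res@achievedHeritability, minHeritability))
    return(res)
  }

  for (attempt in seq_len(maxAttempts)) {
    x <- start
    for (s in seq_len(mixingSteps)) {
      z <- stats::rnorm(ncol(basis))
      u <- drop(basis %*% z)
      nu <- sqrt(sum(u^2))
      if (nu < 1e-14) next
      u <- u / nu
      act <- abs(u) > 1e-12
      lo <- pmin((0 - x[act]) / u[act], (1 - x[act]) / u[act])
      hi <- pmax((0 - x[act]) / u[act], (1 - x[act]) / u[act])
      tLo <- max(lo); tHi <- min(hi)
      if (tHi <= tLo) next
      x <- pmin(pmax(x + stats::runif(1, tLo, tHi) * u, 0), 1)
    }
    res <- finish(x, attempt)
    if (res@achievedHeritability >= minHeritability) return(res)
  }
  stop(sprintf(paste0(
    "infeasible: no table with heritability >= %.3g found in %d attempts ",
    "(binding constraint: minimum heritability; try lowering minHeritability ",
    "or the target prevalence)"), minHeritability, maxAttempts))
}

#' Solve a prevalence-constrained eNME model
#'
#' End-to-end linear solve: build the constraint system, take the
#' minimum-norm solution via complete orthogonal decomposition, and sample
#' a non-degenerate feasible table from the solution polytope (see
#' [sampleFeasibleTable()]).
#'
#' @param spec a [ModelSpec-class] in `"prevalence"` mode.
#' @param seed optional integer seed for reproducibility.
#' @param ... passed to [sampleFeasibleTable()] (`minHeritability`,
#'   `maxAttempts`, `mixingSteps`).
#' @return a [SolverResult-class]; `solverTable()` extracts the solved
#'   [PenetranceTable-class].
#' @examples
#' spec <- modelSpec(c(0.2, 0.2), prevalence = 0.1)
#' res <- solvePrevalenceModel(spec, seed = 1)
#' validateTable(solverTable(res), spec)$passes
#' @export
solvePrevalenceModel <- function(spec, seed = NULL, ...) {
  stopifnot(is(spec, "ModelSpec"))
  if (spec@mode != "prevalence")
    stop("spec is in joint mode; use solveJointModel()")
  if (!is.null(seed)) set.seed(seed)
  sys <- buildLinearSystem(spec)
  mn <- codMinNormSolve(sys)
  res <- sampleFeasibleTable(mn$x, nullSpaceBasis(mn$factors), spec, ...)
  res@seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  res
}

#' @rdname solvePrevalenceModel
#' @export
setMethod("solverTable", "SolverResult", function(object) object@table)

#' @export
setMethod("show", "SolverResult", function(object) {
  cat(sprintf(
    "SolverResult: order-%d table; residual %.3g, heritability %.4f\n",
    object@table@K, object@residualNorm, object@achievedHeritability))
  cat(sprintf("  attempts %d, iterations %d, seed %s\n",
              object@attempts, object@iterations,
              ifelse(is.na(object@seed), "unset", object@seed)))
  invisible(NULL)
})
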