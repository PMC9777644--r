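# Joint (prevalence + heritability) eNME model solving.
#
# Adding the heritability constraint makes the system nonlinear: with the
# denominator cleared, the extra equation is
#
#   sum_i (x_i - P)^2 P(g_i) - h2 * P (1 - P) = 0 ,
#
# a quadratic in x (P is the TARGET prevalence, held fixed by its own
# constraint row).  Newton's method is applied to the stacked residual of
# 3K marginal rows, the prevalence row and the heritability row; each step
# solves the wide linearized system J dx = -F for its minimum-norm
# least-squares solution through the same complete orthogonal
# decomposition machinery as the linear mode.

#' Residual of the joint prevalence + heritability system
#'
#' Stacks, in order: the 3K marginal-penetrance residuals (marginal minus
#' target prevalence), the prevalence residual, and the cleared-denominator
#' heritability residual `sum_i (x_i - P)^2 P(g_i) - h2 P (1 - P)`.
#'
#' @param x candidate penetrance vector of length 3^K (not required to lie
#'   in \[0, 1\]).
#' @param spec a [ModelSpec-class] in joint mode.
#' @return numeric residual vector of length 3K + 2.
#' @export
jointResidual <- function(x, spec) {
  stopifnot(is(spec, "ModelSpec"), spec@mode == "joint")
  if (length(x) != 3L^spec@K)
    stop(sprintf("x must have length 3^K = %d", 3L^spec@K))
  sys <- buildLinearSystem(spec)
  P <- spec@prevalence
  h2 <- spec@heritability
  pg <- sys@A[nrow(sys@A), ]
  unname(c(drop(sys@A %*% x) - sys@b,
           sum((x - P)^2 * pg) - h2 * P * (1 - P)))
}

#' Jacobian of the joint system
#'
#' Rows 1..(3K+1) are the constant linear constraint matrix; the final
#' heritability row has entry `2 (x_i - P) P(g_i)` in column i.
#'
#' @inheritParams jointResidual
#' @return numeric (3K + 2) x 3^K matrix.
#' @export
jointJacobian <- function(x, spec) {
  stopifnot(is(spec, "ModelSpec"), spec@mode == "joint")
  if (length(x) != 3L^spec@K)
    stop(sprintf("x must have length 3^K = %d", 3L^spec@K))
  sys <- buildLinearSystem(spec)
  pg <- sys@A[nrow(sys@A), ]
  unname(rbind(sys@A, 2 * (x - spec@prevalence) * pg))
}

#' One Newton step on the joint system
#'
#' Computes the residual and Jacobian at `x` and takes the minimum-norm
#' least-squares solution of the wide linearized system `J dx = -F`
#' (J has 3K + 2 rows but 3^K columns, so the step itself is
#' under-determined; the minimum-norm choice plays the role of the
#' pseudo-inverse).  At a point where the linearization is inconsistent —
#' e.g. a constant vector, where the heritability row is parallel to the
#' prevalence row — the least-squares step still reduces what can be
#' reduced, and subsequent iterations regain full row rank.
#'
#' @inheritParams jointResidual
#' @return a list with `x` (the updated iterate), `delta` (the step),
#'   `residual` (F at the INPUT x) and `normF` (its max-norm).
#' @export
newtonStep <- function(x, spec) {
  F_ <- jointResidual(x, spec)
  J <- jointJacobian(x, spec)
  delta <- codSolve(codFactor(J), -F_, leastSquares = TRUE)
  list(x = x + delta, delta = delta, residual = F_, normF = max(abs(F_)))
}

#' Solve a jointly constrained eNME model by Newton iteration
#'
#' Finds a penetrance table whose marginal penetrances and prevalence equal
#' the target prevalence and whose heritability equals the target
#' heritability, inside the \[0,1\] box.  Box constraints are not enforced
#' during the iteration (steps stay exact); feasibility is checked only at
#' convergence, and an out-of-box limit triggers a random restart.
#'
#' Restart schedule.  The first attempt starts from the zero vector.
#' Newton converges from almost anywhere on this almost-linear system, but
#' its limit keeps much of the start's dispersion, so restart points must
#' carry roughly the dispersion the heritability target implies:
#' attempts 2-10 draw uniform points centred on the prevalence with
#' half-width `sqrt(3 h2 P (1-P))` (matching the target standard
#' deviation), clipped to \[0,1\].  If those all converge outside the box
#' — typical when the target spread is comparable to the prevalence, so
#' solutions hug the 0 boundary — later restarts are seeded on the linear
#' constraint manifold itself: a feasible prevalence-only table with
#' heritability at least `h2` is drawn by hit-and-run
#' ([sampleFeasibleTable()]) and shrunk toward the constant table, which
#' scales its heritability by exactly the squared shrink factor, landing
#' the start (numerically) on the solution set for Newton to polish.
#'
#' A zero heritability target is accepted and yields the null model (the
#' constant prevalence table, the unique zero-spread solution).
#'
#' @param spec a [ModelSpec-class] in `"joint"` mode.
#' @param seed optional integer seed.
#' @param tol convergence tolerance on the max-norm of the residual.
#'   Default 1e-8.
#' @param maxIter Newton iterations per attempt. Default 100.
#' @param maxRestarts attempts before giving up. Default 50.
#' @return a [SolverResult-class]; `iterations` counts the successful
#'   attempt's Newton steps and `attempts` the starts used.
#' @examples
#' spec <- modelSpec(c(0.2, 0.2), prevalence = 0.1, heritability = 0.05)
#' res <- solveJointModel(spec, seed = 1)
#' validateTable(solverTable(res), spec)$passes
#' @export
solveJointModel <- function(spec, seed = NULL, tol = 1e-8,
                            maxIter = 100L, maxRestarts = 50L) {
  stopifnot(is(spec, "ModelSpec"))
  if (spec@mode != "joint")
    stop("spec is in prevalence mode; use solvePrevalenceModel()")
  if (!is.null(seed)) set.seed(seed)
  n <- 3L^spec@K
  P <- spec@prevalence
  h2 <- spec@heritability
  halfWidth <- sqrt(3 * h2 * P * (1 - P))
  manifold <- NULL   # lazy COD of the linear subsystem for seeded restarts

  startPoint <- function(attempt) {
    if (attempt == 1L) return(numeric(n))
    if (attempt <= 10L)
      return(stats::runif(n, max(0, P - halfWidth), min(1, P + halfWidth)))
    if (is.null(manifold)) {
      sys <- buildLinearSystem(spec)
      manifold <<- list(
        N = nullSpaceBasis(codFactor(sys@A)),
        pg = sys@A[nrow(sys@A), ])
    }
    xh <- heritabilityAscentSeed(manifold$N, manifold$pg, P, h2)
    if (is.null(xh))
      return(stats::runif(n, max(0, P - halfWidth), min(1, P + halfWidth)))
    hx <- sum((xh - P)^2 * manifold$pg) / (P * (1 - P))
    P + sqrt(h2 / hx) * (xh - P)
  }

  for (attempt in seq_len(maxRestarts)) {
    x <- startPoint(attempt)
    prevNorm <- Inf
    growing <- 0L
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
      st <- tryCatch(newtonStep(x, spec), error = function(e) NULL)
      if (is.null(st)) break                     # step failure -> restart
      if (st$normF <= tol) { converged <- TRUE; break }
      growing <- if (st$normF >= prevNorm) growing + 1L else 0L
      if (growing >= 5L) break                   # divergence -> restart
      prevNorm <- st$normF
      x <- st$x
      iter <- iter + 1L
    }
    if (!converged) next
    if (any(x < -1e-10 | x > 1 + 1e-10)) next    # out of box -> restart
    x <- pmin(pmax(x, 0), 1)
    tab <- penetranceTable(x, spec@mafs)
    return(new("SolverResult",
               table = tab,
               residualNorm = sqrt(sum(jointResidual(x, spec)^2)),
               achievedHeritability = heritability(tab),
               attempts = as.integer(attempt),
               iterations = as.integer(iter),
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
  }
  stop(sprintf(paste0(
    "no in-box solution found after %d restarts; the target combination ",
    "may be infeasible.  Solving succeeds most reliably with prevalence ",
    "and heritability below 0.3 for orders 2-3 (0.2 for order 4+) and ",
    "MAFs in [0.05, 0.3]"), maxRestarts))
}

# Random greedy walk on the linear constraint manifold that increases
# heritability until it reaches h2: from the constant table, repeatedly draw
# a null-space direction and jump to whichever end of the feasible [0,1]
# step interval raises the heritability most.  Returns a feasible table with
# heritability >= h2 (to be shrunk back toward the constant table), or NULL
# if the target is not reached (suggesting h2 is near or beyond the maximum
# attainable on the polytope).
heritabilityAscentSeed <- function(N, pg, P, h2, maxMoves = 200L) {
  n <- length(pg)
  x <- rep(P, n)
  denom <- P * (1 - P)
  h <- 0
  if (h2 <= 0) return(x)
  for (move in seq_len(maxMoves)) {
    z <- stats::rnorm(ncol(N))
    u <- drop(N %*% z)
    nu <- sqrt(sum(u^2))
    if (nu < 1e-14) next
    u <- u / nu
    act <- abs(u) > 1e-12
    lo <- pmin((0 - x[act]) / u[act], (1 - x[act]) / u[act])
    hi <- pmax((0 - x[act]) / u[act], (1 - x[act]) / u[act])
    tLo <- max(lo); tHi <- min(hi)
    if (tHi <= tLo) next
    for (t_ in c(tLo, tHi)) {
      cand <- pmin(pmax(x + t_ * u, 0), 1)
      hc <- sum((cand - P)^2 * pg) / denom
      if (hc > h) { x <- cand; h <- hc }
    }
    if (h >= h2) return(x)
  }
  NULL
}
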