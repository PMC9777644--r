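jointSpec2 <- function() modelSpec(c(0.2, 0.2), 0.64, 0.4, warn = FALSE)

test_that("the joint residual stacks marginal, prevalence and heritability terms", {
  spec <- jointSpec2()
  # constant prevalence vector: only the heritability equation is violated
  F0 <- jointResidual(rep(0.64, 9), spec)
  expect_length(F0, 8)
  expect_equal(F0[1:7], rep(0, 7), tolerance = 1e-12)
  expect_equal(F0[8], -0.4 * 0.64 * 0.36, tolerance = 1e-12)
  # the benchmark table satisfies the system to print precision
  expect_lt(max(abs(jointResidual(benchValues, spec))), 2e-3)
  # random point against independent brute-force sums
  set.seed(61)
  x <- runif(9)
  F_ <- jointResidual(x, spec)
  for (snp in 1:2) for (g in 0:2)
    expect_equal(F_[(snp - 1) * 3 + g + 1],
                 bruteMarginal(x, c(0.2, 0.2), snp, g) - 0.64,
                 tolerance = 1e-12)
  expect_equal(F_[7], brutePrevalence(x, c(0.2, 0.2)) - 0.64,
               tolerance = 1e-12)
  P <- 0.64
  pg <- jointFreqs(c(0.2, 0.2))$joint
  expect_equal(F_[8], sum((x - P)^2 * pg) - 0.4 * P * (1 - P),
               tolerance = 1e-12)
})

test_that("the analytic Jacobian matches central finite differences", {
  set.seed(62)
  for (K in 2:4) {
    spec <- modelSpec(runif(K, 0.1, 0.4), 0.2, 0.1, warn = FALSE)
    n <- 3^K
    x <- runif(n)
    J <- jointJacobian(x, spec)
    expect_identical(dim(J), as.integer(c(3 * K + 2, n)))
    h <- 1e-6
    for (j in sample(n, min(n, 6))) {
      e <- numeric(n); e[j] <- h
      fd <- (jointResidual(x + e, spec) - jointResidual(x - e, spec)) / (2 * h)
      expect_equal(J[, j], fd, tolerance = 1e-5)
    }
    # linear rows are constant in x; heritability row vanishes at the constant
    J2 <- jointJacobian(runif(n), spec)
    expect_equal(J[1:(3 * K + 1), ], J2[1:(3 * K + 1), ], tolerance = 1e-15)
    Jc <- jointJacobian(rep(spec@prevalence, n), spec)
    expect_equal(Jc[3 * K + 2, ], rep(0, n), tolerance = 1e-15)
  }
})

test_that("Newton steps behave like Newton steps", {
  spec <- jointSpec2()
  # from a solution, the step is (numerically) zero
  sol <- solverTable(solveJointModel(modelSpec(c(0.2, 0.2), 0.1, 0.05),
                                     seed = 1))@values
  st <- newtonStep(sol, modelSpec(c(0.2, 0.2), 0.1, 0.05))
  expect_lt(max(abs(st$delta)), 1e-6)
  # a step from zero reduces the residual norm
  s0 <- newtonStep(numeric(9), spec)
  expect_lt(max(abs(jointResidual(s0$x, spec))), s0$normF)
  # on the purely linear subsystem one minimum-norm step is exact
  lin <- buildLinearSystem(spec)
  x1 <- codSolve(codFactor(lin@A), lin@b)
  expect_lt(max(abs(lin@A %*% x1 - lin@b)), 1e-10)
})

test_that("joint solves meet both targets at 1e-6 for the published ranges", {
  combos <- list(
    list(m = c(0.1, 0.4), P = 0.2, h = 0.1),
    list(m = c(0.2, 0.3), P = 0.1, h = 0.05),
    list(m = c(0.1, 0.4, 0.2), P = 0.2, h = 0.05),
    list(m = c(0.1, 0.4, 0.2), P = 0.1, h = 0.1))
  for (i in seq_along(combos)) {
    cb <- combos[[i]]
    spec <- modelSpec(cb$m, cb$P, cb$h, warn = FALSE)
    res <- solveJointModel(spec, seed = 70 + i)
    v <- validateTable(solverTable(res), spec, tol = 1e-6)
    expect_true(v$passes)
    expect_lt(abs(res@achievedHeritability - cb$h), 1e-6)
    expect_true(all(res@table@values >= 0 & res@table@values <= 1))
  }
})

test_that("a zero heritability target returns the null model", {
  spec <- modelSpec(c(0.2, 0.2), 0.1, 0)
  res <- solveJointModel(spec, seed = 2)
  expect_lt(res@achievedHeritability, 1e-6)
  expect_equal(prevalence(solverTable(res)), 0.1, tolerance = 1e-6)
})

test_that("prevalence-mode statistics round-trip through joint mode", {
  spec <- modelSpec(c(0.2, 0.2), 0.64, warn = FALSE)
  lin <- solvePrevalenceModel(spec, seed = 8)
  h2 <- lin@achievedHeritability
  back <- solveJointModel(modelSpec(c(0.2, 0.2), 0.64, h2, warn = FALSE),
                          seed = 8)
  tab <- solverTable(back)
  expect_equal(prevalence(tab), 0.64, tolerance = 1e-6)
  expect_equal(heritability(tab), h2, tolerance = 1e-6)
})

test_that("joint solves are deterministic under a fixed seed", {
  spec <- modelSpec(c(0.2, 0.3), 0.2, 0.05)
  a <- solveJointModel(spec, seed = 77)
  b <- solveJointModel(spec, seed = 77)
  expect_identical(a@table@values, b@table@values)
  expect_identical(a@iterations, b@iterations)
})
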