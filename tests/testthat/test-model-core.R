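test_that("Hardy-Weinberg genotype frequencies are correct and sum to 1", {
  expect_equal(genotypeFreqs(0.2), c(AA = 0.64, Aa = 0.32, aa = 0.04))
  expect_equal(unname(genotypeFreqs(0)), c(1, 0, 0))
  expect_equal(unname(genotypeFreqs(0.5)), c(0.25, 0.5, 0.25))
  for (p in seq(0, 0.5, by = 0.05))
    expect_equal(sum(genotypeFreqs(p)), 1, tolerance = 1e-12)
  expect_error(genotypeFreqs(0.6), "0.5")
  expect_error(genotypeFreqs(-0.1), "0.5")
})

test_that("joint frequencies factorize over SNPs and sum to 1", {
  f <- jointFreqs(modelSpec(c(0.2, 0.2), 0.1))
  expect_equal(f$joint[1], 0.64 * 0.64)
  expect_equal(sum(f$joint), 1, tolerance = 1e-12)
  # reduces to single-SNP frequencies at K = 1
  expect_equal(jointFreqs(0.2)$joint, unname(genotypeFreqs(0.2)))
  # factorization property for K up to 5
  set.seed(11)
  for (K in 2:5) {
    mafs <- runif(K, 0.05, 0.5)
    f <- jointFreqs(mafs)
    expect_equal(sum(f$joint), 1, tolerance = 1e-10)
    expect_equal(rowSums(f$perSnp), rep(1, K), tolerance = 1e-12)
    # spot-check random cells against the digit-wise product
    for (i in sample(3^K, 5)) {
      d <- cellDigits(i, K)
      expect_equal(f$joint[i], bruteCellFreq(mafs, d), tolerance = 1e-12)
    }
  }
})

test_that("cell indexing follows the canonical order and round-trips", {
  expect_identical(cellIndex(c(0, 0)), 1L)  # the (AA, BB) corner cell
  expect_identical(cellIndex(c(2, 2)), 9L)  # the (aa, bb) corner cell
  expect_identical(cellIndex(c(1, 0)), 2L)  # SNP 1 varies fastest
  for (K in 2:4)
    for (i in sample(3^K, 8))
      expect_identical(cellIndex(cellDigits(i, K)), i)
  # matrix form agrees with row-wise calls
  m <- allCellDigits <- cellDigits(1:9, 2)
  expect_identical(cellIndex(m), 1:9)
  expect_error(cellIndex(c(3, 0)), "0, 1, 2")
  expect_error(cellDigits(10, 2), "\\[1, 9\\]")
})

test_that("prevalence matches the benchmark model and a brute-force sum", {
  expect_equal(prevalence(benchTable()), 0.64, tolerance = 5e-4)
  # constant table: prevalence equals the constant
  expect_equal(prevalence(penetranceTable(rep(0.37, 27), c(0.1, 0.2, 0.3))),
               0.37, tolerance = 1e-12)
  # random order-3 table against the explicit 27-term sum
  set.seed(21)
  vals <- runif(27)
  mafs <- c(0.12, 0.34, 0.25)
  expect_equal(prevalence(penetranceTable(vals, mafs)),
               brutePrevalence(vals, mafs), tolerance = 1e-12)
})

test_that("heritability matches the benchmark model and a brute-force sum", {
  expect_equal(heritability(benchTable()), 0.4, tolerance = 1e-3)
  expect_equal(heritability(penetranceTable(rep(0.3, 9), c(0.2, 0.2))), 0)
  set.seed(22)
  vals <- runif(9)
  mafs <- c(0.15, 0.42)
  expect_equal(heritability(penetranceTable(vals, mafs)),
               bruteHeritability(vals, mafs), tolerance = 1e-12)
  # degenerate tables have no defined heritability
  expect_error(heritability(penetranceTable(rep(0, 9), c(0.2, 0.2))),
               "degenerate")
  expect_error(heritability(penetranceTable(rep(1, 9), c(0.2, 0.2))),
               "degenerate")
})

test_that("marginal penetrances of the benchmark model equal its prevalence", {
  tab <- benchTable()
  # the three SNP1 marginals, frequency-weighted sums over SNP2
  expect_equal(marginalPenetrance(tab, 1, 0),
               0.64 * 0.4865 + 0.32 * 0.9473 + 0.04 * 0.6401,
               tolerance = 1e-12)
  expect_equal(marginalPenetrance(tab, 1, 1),
               0.64 * 0.9601 + 0.32 * 0.0042 + 0.04 * 0.6065,
               tolerance = 1e-12)
  for (snp in 1:2) for (g in 0:2)
    expect_equal(marginalPenetrance(tab, snp, g), 0.64, tolerance = 5e-4)
  # constant table: every marginal equals the constant
  ctab <- penetranceTable(rep(0.25, 27), c(0.1, 0.2, 0.3))
  for (snp in 1:3) for (g in 0:2)
    expect_equal(marginalPenetrance(ctab, snp, g), 0.25, tolerance = 1e-12)
  expect_error(marginalPenetrance(tab, 3, 0), "snp")
  expect_error(marginalPenetrance(tab, 1, 5), "genotype")
})

test_that("marginal penetrance agrees with an independent summation oracle", {
  set.seed(23)
  vals <- runif(27)
  mafs <- c(0.2, 0.35, 0.1)
  tab <- penetranceTable(vals, mafs)
  for (snp in 1:3) for (g in 0:2)
    expect_equal(marginalPenetrance(tab, snp, g),
                 bruteMarginal(vals, mafs, snp, g), tolerance = 1e-12)
})

test_that("law of total probability ties marginals to prevalence", {
  set.seed(24)
  for (rep_ in 1:5) {
    K <- sample(2:4, 1)
    mafs <- runif(K, 0.05, 0.5)
    tab <- penetranceTable(runif(3^K), mafs)
    f <- jointFreqs(mafs)
    for (snp in seq_len(K)) {
      total <- sum(vapply(0:2, function(g)
        marginalPenetrance(tab, snp, g) * f$perSnp[snp, g + 1], numeric(1)))
      expect_equal(total, prevalence(tab), tolerance = 1e-10)
    }
  }
})

test_that("validateTable passes the benchmark model and flags perturbations", {
  tab <- benchTable()
  spec <- benchSpec()
  expect_true(validateTable(tab, spec, tol = 1e-3)$passes)
  # constant table against its own prevalence: passes with zero heritability
  cspec <- modelSpec(c(0.2, 0.2), 0.3)
  expect_true(validateTable(penetranceTable(rep(0.3, 9), c(0.2, 0.2)),
                            cspec, tol = 1e-12)$passes)
  # perturbing one cell breaks the marginals it participates in
  vals <- benchValues
  vals[5] <- vals[5] + 0.1
  rep_ <- validateTable(penetranceTable(vals, c(0.2, 0.2)), spec, tol = 1e-3)
  expect_false(rep_$passes)
  flagged <- rep_$marginals[abs(rep_$marginals$deviation) > 1e-3, ]
  # cell 5 = (Aa, Bb): exactly the SNP1-Aa and SNP2-Bb marginals move
  expect_setequal(paste(flagged$snp, flagged$genotype),
                  c("1 1", "2 1"))
  expect_equal(
    rep_$marginals$marginal[rep_$marginals$snp == 1 &
                              rep_$marginals$genotype == 1],
    bruteMarginal(vals, c(0.2, 0.2), 1, 1), tolerance = 1e-12)
})

test_that("model specs validate their invariants", {
  expect_error(modelSpec(0.2, 0.1), "K must be")
  expect_error(modelSpec(c(0.2, 0.6), 0.1), "MAF")
  expect_error(modelSpec(c(0.2, 0), 0.1), "MAF")
  expect_error(modelSpec(c(0.2, 0.2), 1.2), "prevalence")
  expect_error(modelSpec(c(0.2, 0.2), 0.1, heritability = 1.5), "heritability")
  expect_identical(modelSpec(c(0.2, 0.2), 0.1)@mode, "prevalence")
  expect_identical(modelSpec(c(0.2, 0.2), 0.1, 0.05)@mode, "joint")
  # recommended-range checks warn, never error
  expect_warning(modelSpec(c(0.2, 0.2), 0.5), "recommended")
  expect_warning(modelSpec(c(0.02, 0.2), 0.1), "0.05")
  expect_warning(modelSpec(rep(0.2, 4), 0.25), "0.2")
  expect_silent(modelSpec(c(0.2, 0.2), 0.1))
})
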