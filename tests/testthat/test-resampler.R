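test_that("panels round-trip through both file dialects", {
  p <- genotypePanel(matrix(c(1L, 2L, 3L, 1L, 2L, 2L), 2, 3),
                     labels = c(0, 1), snpIds = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".txt")
  writePanel(p, path)
  q <- readPanel(path)
  expect_identical(q@genotypes, p@genotypes)
  expect_identical(q@labels, p@labels)
  expect_identical(q@snpIds, p@snpIds)
  # additive 0/1/2 coding is shifted back to {1,2,3} on read
  writePanel(p, path, dialect = "additive012")
  q2 <- readPanel(path, dialect = "additive012")
  expect_identical(q2@genotypes, p@genotypes)
  expect_null(sampleLabels(q2))
})

test_that("parse errors name the offending line and column", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("label\ts1\ts2", "0\t1\t4", "1\t2\t3"), path)
  expect_error(readPanel(path), "line 2, column 3")
  writeLines(c("0\t1\t2", "1\t2"), path)
  expect_error(readPanel(path), "ragged")
  writeLines(c("2\t1\t2", "1\t2\t3"), path)
  expect_error(readPanel(path), "label")
})

test_that("window selection returns contiguous in-range columns", {
  set.seed(81)
  ref <- synthReferencePanel(20, 30, seed = 81)
  w <- selectWindow(ref, 30)
  expect_identical(w@genotypes, ref@genotypes)  # full-width window
  w1 <- selectWindow(ref, 1)
  expect_identical(ncol(w1@genotypes), 1L)
  expect_true(w1@snpIds %in% ref@snpIds)
  set.seed(5); a <- selectWindow(ref, 7)
  set.seed(5); b <- selectWindow(ref, 7)
  expect_identical(a@snpIds, b@snpIds)
  # windows are contiguous blocks of the original columns
  idx <- match(a@snpIds, ref@snpIds)
  expect_identical(idx, idx[1]:(idx[1] + 6L))
  expect_error(selectWindow(ref, 31), "width")
})

test_that("case removal keeps controls in order", {
  g <- matrix(rep(1:3, 3), 3, 3)
  p <- genotypePanel(g, labels = c(0, 1, 0))
  d <- dropCases(p)
  expect_identical(d@genotypes, g[c(1, 3), ])
  expect_identical(d@labels, c(0L, 0L))
  expect_identical(dropCases(genotypePanel(g, labels = c(0, 0, 0)))@genotypes, g)
  expect_error(dropCases(genotypePanel(g, labels = c(1, 1, 1))), "control")
  expect_error(dropCases(genotypePanel(g)), "label")
})

test_that("segment plans partition the columns", {
  expect_identical(segmentBounds(makeSegments(10, 1)),
                   cbind(first = 1L, last = 10L))
  allSingle <- makeSegments(6, 6)
  expect_identical(segmentBounds(allSingle)[, "first"], 1:6)
  expect_identical(segmentBounds(allSingle)[, "last"], 1:6)
  set.seed(82)
  plan <- makeSegments(1000, 50)
  b <- segmentBounds(plan)
  expect_identical(nSegments(plan), 50L)
  expect_true(all(b[, "last"] >= b[, "first"]))          # non-empty
  expect_identical(unname(b[-1, "first"]), unname(b[-50, "last"] + 1L))
  expect_identical(unname(b[1, "first"]), 1L)
  expect_identical(unname(b[50, "last"]), 1000L)
  expect_error(makeSegments(10, 11), "nSegments")
})

test_that("every output segment is an exact copy of some source row", {
  set.seed(83)
  src <- synthReferencePanel(200, 120, ldRho = 0.4, seed = 83)
  src <- dropCases(src)
  plan <- makeSegments(120, 8)
  sim <- resamplePanel(src, plan, 60)
  expect_identical(nrow(sim@genotypes), 60L)
  b <- segmentBounds(plan)
  for (i in seq_len(nrow(sim@genotypes))) {
    for (s in seq_len(nrow(b))) {
      cols <- b[s, 1]:b[s, 2]
      seg <- sim@genotypes[i, cols]
      hit <- any(apply(src@genotypes[, cols, drop = FALSE], 1,
                       function(r) all(r == seg)))
      expect_true(hit)
    }
  }
  # one-segment plans copy whole rows; one-row sources are copied verbatim
  whole <- resamplePanel(src, makeSegments(120, 1), 10)
  for (i in 1:10)
    expect_true(any(apply(src@genotypes, 1,
                          function(r) all(r == whole@genotypes[i, ]))))
  one <- genotypePanel(src@genotypes[1, , drop = FALSE])
  rep_ <- resamplePanel(one, plan, 5)
  for (i in 1:5)
    expect_identical(rep_@genotypes[i, ], src@genotypes[1, ])
})

test_that("resampling is deterministic under a seed", {
  src <- synthReferencePanel(50, 40, seed = 84)
  set.seed(1); plan <- makeSegments(40, 5); a <- resamplePanel(src, plan, 20)
  set.seed(1); plan2 <- makeSegments(40, 5); b <- resamplePanel(src, plan2, 20)
  expect_identical(a@genotypes, b@genotypes)
  set.seed(2); c_ <- resamplePanel(src, makeSegments(40, 5), 20)
  expect_false(identical(a@genotypes, c_@genotypes))
})

test_that("resampling preserves within-segment joint genotype structure", {
  set.seed(85)
  src <- synthReferencePanel(400, 60, ldRho = 0.7, seed = 85)
  plan <- makeSegments(60, 3)
  sim <- resamplePanel(src, plan, 2000)
  b <- segmentBounds(plan)
  # two adjacent SNPs inside the first sufficiently long segment
  seg <- which(b[, 2] - b[, 1] >= 1)[1]
  j <- b[seg, 1]
  srcTab <- table(factor(src@genotypes[, j], 1:3),
                  factor(src@genotypes[, j + 1], 1:3))
  simTab <- table(factor(sim@genotypes[, j], 1:3),
                  factor(sim@genotypes[, j + 1], 1:3))
  pSrc <- as.vector(srcTab) / sum(srcTab)
  occ <- pSrc > 0
  chi <- suppressWarnings(
    stats::chisq.test(as.vector(simTab)[occ], p = pSrc[occ] / sum(pSrc[occ])))
  expect_gt(chi$p.value, 0.001)
  # cells absent from the source stay absent in the output
  expect_true(all(as.vector(simTab)[!occ] == 0))
})
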