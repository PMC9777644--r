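# Shared fixtures built in code.

# A published benchmark two-locus model without marginal effects:
# MAFs (0.2, 0.2), prevalence 0.64, heritability 0.4, values printed to
# four decimals.  Canonical cell order (SNP 1 varies fastest).
benchValues <- c(0.4865, 0.9601, 0.5377,
                 0.9473, 0.0042, 0.8113,
                 0.6401, 0.6065, 0.9089)
benchTable <- function() penetranceTable(benchValues, mafs = c(0.2, 0.2))
benchSpec <- function() modelSpec(c(0.2, 0.2), prevalence = 0.64, warn = FALSE)

# Brute-force oracles, written independently of the package internals:
# loop over every cell, build its joint frequency digit by digit.
bruteCellFreq <- function(mafs, digits) {
  prod(vapply(seq_along(mafs), function(k) {
    p <- mafs[k]
    c((1 - p)^2, 2 * p * (1 - p), p^2)[digits[k] + 1]
  }, numeric(1)))
}

brutePrevalence <- function(values, mafs) {
  K <- length(mafs)
  total <- 0
  for (i in seq_along(values)) {
    d <- integer(K); ii <- i - 1
    for (k in seq_len(K)) { d[k] <- ii %% 3; ii <- ii %/% 3 }
    total <- total + values[i] * bruteCellFreq(mafs, d)
  }
  total
}

bruteHeritability <- function(values, mafs) {
  P <- brutePrevalence(values, mafs)
  K <- length(mafs)
  num <- 0
  for (i in seq_along(values)) {
    d <- integer(K); ii <- i - 1
    for (k in seq_len(K)) { d[k] <- ii %% 3; ii <- ii %/% 3 }
    num <- num + (values[i] - P)^2 * bruteCellFreq(mafs, d)
  }
  num / (P * (1 - P))
}

bruteMarginal <- function(values, mafs, snp, genotype) {
  K <- length(mafs)
  total <- 0
  for (i in seq_along(values)) {
    d <- integer(K); ii <- i - 1
    for (k in seq_len(K)) { d[k] <- ii %% 3; ii <- ii %/% 3 }
    if (d[snp] != genotype) next
    w <- 1
    for (k in seq_len(K)) if (k != snp)
      w <- w * bruteCellFreq(mafs[k], d[k])
    total <- total + values[i] * w
  }
  total
}
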