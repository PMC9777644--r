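#' Generate a synthetic reference genotype panel
#'
#' Emulates a real case-control SNP matrix (samples x SNPs, genotypes
#' \{1, 2, 3\}, 0/1 labels) so the full resampling pipeline runs without
#' external data.  Two haplotypes per sample are generated left to right by
#' a first-order process: at each SNP a haplotype copies its allele from
#' the previous SNP with probability `ldRho`, and otherwise draws a fresh
#' Bernoulli(MAF_k) allele.  The genotype is 1 + (allele sum).  With
#' `ldRho = 0` every SNP is an independent Hardy-Weinberg draw at its MAF;
#' increasing `ldRho` adds local correlation between adjacent SNPs (and,
#' when neighboring MAFs differ, pulls marginal frequencies toward their
#' neighbors).  Labels are i.i.d. Bernoulli(`labelRate`), independent of
#' genotype.
#'
#' @param nSamples number of samples (rows).
#' @param nSnps number of SNPs (columns).
#' @param mafs per-SNP MAF vector (recycled), or `NULL` to draw each SNP's
#'   MAF uniformly from `mafRange`.
#' @param mafRange range MAFs are drawn from when `mafs` is `NULL`.
#'   Default `c(0.05, 0.5)`.
#' @param ldRho adjacent-SNP allele copy probability, in \[0, 1).
#'   Default 0.
#' @param labelRate probability a sample is labeled a case. Default 0.5.
#' @param seed optional integer seed.
#' @return a labeled [GenotypePanel-class].
#' @examples
#' ref <- synthReferencePanel(500, 100, ldRho = 0.5, seed = 1)
#' summary(computeMAF(ref))
#' @export
synthReferencePanel <- function(nSamples, nSnps, mafs = NULL,
                                mafRange = c(0.05, 0.5), ldRho = 0,
                                labelRate = 0.5, seed = NULL) {
  nSamples <- as.integer(nSamples); nSnps <- as.integer(nSnps)
  if (nSamples < 1L || nSnps < 1L)
    stop("nSamples and nSnps must be positive")
  if (length(ldRho) != 1L || is.na(ldRho) || ldRho < 0 || ldRho >= 1)
    stop("ldRho must lie in [0, 1)")
  if (labelRate < 0 || labelRate > 1)
    stop("labelRate must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mafs)) {
    if (length(mafRange) != 2L || mafRange[1L] > mafRange[2L] ||
        mafRange[1L] < 0 || mafRange[2L] > 0.5)
      stop("mafRange must be an increasing pair within [0, 0.5]")
    mafs <- stats::runif(nSnps, mafRange[1L], mafRange[2L])
  } else {
    mafs <- rep_len(as.numeric(mafs), nSnps)
    if (any(mafs < 0) || any(mafs > 0.5))
      stop("per-SNP MAFs must lie in [0, 0.5]")
  }
  hap <- function() {
    h <- matrix(0L, nSamples, nSnps)
    h[, 1L] <- stats::rbinom(nSamples, 1L, mafs[1L])
    for (k in seq_len(nSnps)[-1L]) {
      copy <- stats::rbinom(nSamples, 1L, ldRho)
      fresh <- stats::rbinom(nSamples, 1L, mafs[k])
      h[, k] <- ifelse(copy == 1L, h[, k - 1L], fresh)
    }
    h
  }
  g <- 1L + hap() + hap()
  genotypePanel(g, labels = stats::rbinom(nSamples, 1L, labelRate))
}
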