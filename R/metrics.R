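# Validation metrics: per-SNP MAFs, simulated-vs-reference concordance,
# empirical penetrance recovery.

#' Per-SNP minor allele frequencies of a panel
#'
#' Counts rare-allele copies per column (codes 1/2/3 carry 0/1/2 copies)
#' over 2n alleles, then folds at 0.5 (`min(p, 1 - p)`) because the
#' simulated minor allele may flip relative to the reference coding.
#'
#' @param panel a non-empty [GenotypePanel-class].
#' @return numeric vector of per-SNP MAFs in \[0, 0.5\], named by SNP id.
#' @examples
#' p <- genotypePanel(matrix(c(1L, 2L, 3L, 1L), 4, 1))
#' computeMAF(p)  # (0 + 1 + 2 + 0) / 8 = 0.375
#' @export
computeMAF <- function(panel) {
  stopifnot(is(panel, "GenotypePanel"))
  if (nrow(panel@genotypes) == 0L) stop("panel has no samples")
  p <- colMeans(panel@genotypes - 1L) / 2
  stats::setNames(pmin(p, 1 - p), panel@snpIds)
}

#' MAF concordance between a simulated and a reference panel
#'
#' For each SNP, compares the reference MAF with the simulated MAF and a
#' 95% binomial confidence interval for the simulated estimate (normal
#' approximation on 2n alleles, `p +- 1.96 sqrt(p(1-p)/(2n))`, clipped to
#' \[0, 0.5\]).  A faithful resampler keeps nearly all reference MAFs
#' inside their bands.
#'
#' @param sim simulated [GenotypePanel-class].
#' @param ref reference [GenotypePanel-class] of equal width with matching
#'   SNP ids.
#' @return a list with `perSnp` (data.frame: `snp_id`, `ref_maf`,
#'   `sim_maf`, `ci_lo`, `ci_hi`, `inside`) and `fractionInside` (share of
#'   SNPs whose reference MAF lies inside the simulated band).
#' @export
mafConcordance <- function(sim, ref) {
  stopifnot(is(sim, "GenotypePanel"), is(ref, "GenotypePanel"))
  if (ncol(sim@genotypes) != ncol(ref@genotypes))
    stop("simulated and reference panels must have the same number of SNPs")
  if (!identical(sim@snpIds, ref@snpIds))
    stop("simulated and reference SNP ids do not match")
  simMaf <- computeMAF(sim)
  refMaf <- computeMAF(ref)
  nAll <- 2 * nrow(sim@genotypes)
  half <- 1.96 * sqrt(simMaf * (1 - simMaf) / nAll)
  lo <- pmax(simMaf - half, 0)
  hi <- pmin(simMaf + half, 0.5)
  inside <- refMaf >= lo & refMaf <= hi
  perSnp <- data.frame(
    snp_id = sim@snpIds,
    ref_maf = unname(refMaf),
    sim_maf = unname(simMaf),
    ci_lo = unname(lo),
    ci_hi = unname(hi),
    inside = unname(inside),
    stringsAsFactors = FALSE)
  list(perSnp = perSnp, fractionInside = mean(inside))
}

#' Empirical penetrance of a labeled panel at given loci
#'
#' Tabulates, for every genotype cell of the K chosen loci, the number of
#' samples, the number of cases and the case fraction.  On an unfiltered
#' labeled stream these fractions converge to the embedded penetrance
#' values; after case/control truncation they are distorted by the imposed
#' ratio.
#'
#' @param panel a labeled [GenotypePanel-class].
#' @param loci K distinct column indices.
#' @return data.frame with one row per cell in canonical order:
#'   `cell` (1-based index), `genotype` (digit string like `"0,1"`),
#'   `n`, `cases`, `fraction` (NA for empty cells), `occupied`.
#' @export
empiricalPenetrance <- function(panel, loci) {
  stopifnot(is(panel, "GenotypePanel"))
  if (!length(panel@labels)) stop("panel has no labels")
  loci <- as.integer(loci)
  if (any(loci < 1L) || any(loci > ncol(panel@genotypes)))
    stop("loci out of range")
  K <- length(loci)
  cells <- cellIndex(panel@genotypes[, loci, drop = FALSE] - 1L)
  nCells <- 3L^K
  n <- tabulate(cells, nCells)
  cases <- tabulate(cells[panel@labels == 1L], nCells)
  digs <- allCellDigits(K)
  data.frame(
    cell = seq_len(nCells),
    genotype = apply(digs, 1L, paste, collapse = ","),
    n = n,
    cases = cases,
    fraction = ifelse(n > 0L, cases / pmax(n, 1L), NA_real_),
    occupied = n > 0L,
    stringsAsFactors = FALSE)
}
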