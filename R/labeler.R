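# Embedding a solved model: probabilistic case/control labeling.

#' Create an embedding plan
#'
#' @param loci K distinct column indices carrying the model SNPs.
#' @param table the [PenetranceTable-class] to embed.
#' @param nCases,nControls target sample counts of the final dataset.
#' @return an [EmbeddingPlan-class].
#' @export
embeddingPlan <- function(loci, table, nCases, nControls) {
  new("EmbeddingPlan",
      loci = as.integer(loci), table = table,
      nCases = as.integer(nCases), nControls = as.integer(nControls))
}

#' Choose model loci whose panel MAFs match the table's MAFs
#'
#' The model's statistics (prevalence, heritability, absent marginals) hold
#' only at the MAFs the table was solved under, so the embedding columns
#' should carry those frequencies.  For each model SNP k this picks, at
#' random, a distinct panel column whose empirical MAF is within `tol` of
#' `modelMafs(table)[k]`.
#'
#' @param panel a [GenotypePanel-class].
#' @param table a [PenetranceTable-class].
#' @param tol MAF matching tolerance. Default 0.05.
#' @return integer vector of K column indices.
#' @export
selectModelLoci <- function(panel, table, tol = 0.05) {
  stopifnot(is(panel, "GenotypePanel"), is(table, "PenetranceTable"))
  mafs <- computeMAF(panel)
  chosen <- integer()
  for (k in seq_len(table@K)) {
    target <- table@mafs[k]
    eligible <- setdiff(which(abs(mafs - target) <= tol), chosen)
    if (!length(eligible)) {
      nearest <- sort(abs(mafs - target))[seq_len(min(3L, length(mafs)))]
      stop(sprintf(
        "no panel column has MAF within %.3g of model SNP %d's MAF %.3g (nearest deviations: %s)",
        tol, k, target, paste(signif(nearest, 3), collapse = ", ")))
    }
    chosen <- c(chosen, if (length(eligible) == 1L) eligible else
      sample(eligible, 1L))
  }
  chosen
}

#' Assign case/control labels from a penetrance table
#'
#' Each sample is labeled a case (1) with probability equal to the
#' penetrance of its genotype combination at the model loci, and a control
#' (0) otherwise.
#'
#' @param genoAtLoci integer matrix (samples x K) of genotype codes
#'   \{1, 2, 3\} at the model loci, in model-SNP order, or a single length-K
#'   vector.
#' @param table a [PenetranceTable-class] of matching order.
#' @return integer vector of 0/1 labels, one per sample.
#' @examples
#' tab <- penetranceTable(c(0, rep(1, 8)), mafs = c(0.2, 0.2))
#' assignLabels(c(1, 1), tab)  # the (AA, BB) cell has penetrance 0 -> control
#' @export
assignLabels <- function(genoAtLoci, table) {
  stopifnot(is(table, "PenetranceTable"))
  g <- if (is.matrix(genoAtLoci)) genoAtLoci else
    matrix(genoAtLoci, nrow = 1L)
  if (ncol(g) != table@K)
    stop(sprintf("genotypes must have %d columns (the model order)", table@K))
  if (anyNA(g) || any(g < 1L) || any(g > 3L))
    stop("genotype codes must be in {1, 2, 3}")
  cells <- cellIndex(g - 1L)
  p <- table@values[cells]
  as.integer(stats::rbinom(nrow(g), 1L, p))
}

#' Generate a case-control dataset with exact group sizes
#'
#' Streams resampled samples ([resamplePanel()]) through probabilistic
#' labeling ([assignLabels()]) and retains them until exactly `nCases`
#' cases and `nControls` controls have accumulated; the excess of whichever
#' class fills first is discarded, and the final rows are shuffled.
#' Genotypes are never modified by labeling.
#'
#' Note that fixing the case:control ratio distorts the *conditional* case
#' fractions of the final dataset relative to the penetrance values; the
#' penetrance is recovered on the pre-truncation stream (see
#' [empiricalPenetrance()] and the vignette).
#'
#' @param source a [GenotypePanel-class] to resample from.
#' @param plan a [SegmentPlan-class] covering the source width.
#' @param embedding an [EmbeddingPlan-class]; its loci index columns of the
#'   source/simulated panel.
#' @param seed optional integer seed.
#' @param maxDraws stall guard: abort if the quotas are unfilled after this
#'   many streamed samples (e.g. a zero-penetrance table with cases
#'   requested). Default 1e6.
#' @return a labeled [GenotypePanel-class] with `nCases + nControls` rows.
#' @export
generateCaseControl <- function(source, plan, embedding, seed = NULL,
                                maxDraws = 1e6) {
  stopifnot(is(source, "GenotypePanel"), is(plan, "SegmentPlan"),
            is(embedding, "EmbeddingPlan"))
  if (any(embedding@loci > plan@nSnps))
    stop("embedding loci fall outside the panel width")
  if (!is.null(seed)) set.seed(seed)
  needCase <- embedding@nCases
  needCtrl <- embedding@nControls
  keptG <- vector("list", 0L)
  keptL <- integer()
  drawn <- 0L
  while (needCase > 0L || needCtrl > 0L) {
    if (drawn >= maxDraws)
      stop(sprintf(
        "labeling stalled: %d case and %d control samples still missing after %d draws (acceptance rate too low for the requested counts)",
        needCase, needCtrl, drawn))
    batch <- min(max(1000L, 2L * (needCase + needCtrl)),
                 as.integer(maxDraws - drawn))
    sim <- resamplePanel(source, plan, batch)
    drawn <- drawn + batch
    lab <- assignLabels(sim@genotypes[, embedding@loci, drop = FALSE],
                        embedding@table)
    takeCase <- which(lab == 1L)[seq_len(min(needCase, sum(lab == 1L)))]
    takeCtrl <- which(lab == 0L)[seq_len(min(needCtrl, sum(lab == 0L)))]
    take <- c(takeCase, takeCtrl)
    if (length(take)) {
      keptG[[length(keptG) + 1L]] <- sim@genotypes[take, , drop = FALSE]
      keptL <- c(keptL, lab[take])
      needCase <- needCase - length(takeCase)
      needCtrl <- needCtrl - length(takeCtrl)
    }
  }
  g <- do.call(rbind, keptG)
  ord <- sample.int(nrow(g))
  genotypePanel(g[ord, , drop = FALSE], labels = keptL[ord],
                snpIds = source@snpIds)
}
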