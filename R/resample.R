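#' Partition panel columns into random contiguous segments
#'
#' Draws `nSegments - 1` distinct interior breakpoints uniformly at random,
#' yielding `nSegments` contiguous, non-empty segments that cover columns
#' 1..nSnps exactly once.  Each segment therefore has a random number of
#' SNPs.  One plan is drawn per generated dataset; all output samples of
#' that dataset share the segmentation.
#'
#' @param nSnps number of columns to partition.
#' @param nSegments number of segments, between 1 and `nSnps`.  Default:
#'   one segment per 20 SNPs (at least 1).
#' @param object a `SegmentPlan` (accessor methods).
#' @return a [SegmentPlan-class].
#' @examples
#' plan <- makeSegments(100, nSegments = 5)
#' segmentBounds(plan)
#' @export
makeSegments <- function(nSnps, nSegments = max(1L, nSnps %/% 20L)) {
  nSnps <- as.integer(nSnps)
  nSegments <- as.integer(nSegments)
  if (nSnps < 1L) stop("nSnps must be positive")
  if (nSegments < 1L || nSegments > nSnps)
    stop(sprintf("nSegments must be in [1, %d]", nSnps))
  interior <- if (nSegments > 1L)
    sort(sample(2:nSnps, nSegments - 1L)) else integer()
  new("SegmentPlan", starts = as.integer(c(1L, interior)), nSnps = nSnps)
}

#' @rdname makeSegments
#' @export
setMethod("nSegments", "SegmentPlan", function(object) length(object@starts))

#' @describeIn makeSegments matrix of 1-based first/last columns, one row
#'   per segment.
#' @export
setMethod("segmentBounds", "SegmentPlan", function(object) {
  s <- object@starts
  cbind(first = s, last = c(s[-1L] - 1L, object@nSnps))
})

#' @export
setMethod("show", "SegmentPlan", function(object) {
  b <- segmentBounds(object)
  cat(sprintf("SegmentPlan: %d segments over %d SNPs (lengths %s)\n",
              nrow(b), object@nSnps,
              paste(utils::head(b[, 2L] - b[, 1L] + 1L, 10L), collapse = ", ")))
  invisible(NULL)
})

#' Generate simulated samples by segment-wise resampling
#'
#' Each output sample is spliced together segment by segment: for every
#' segment of the plan, one source row is chosen uniformly at random (with
#' replacement, independently across segments and output rows) and its
#' genotypes over that segment are copied verbatim.  Within a segment the
#' output therefore reproduces the source's joint genotype distribution —
#' minor allele frequencies and local linkage disequilibrium included —
#' while across segment boundaries genotypes mix independently.
#'
#' @param source a [GenotypePanel-class] (typically the control rows of a
#'   reference window; see [dropCases()]).
#' @param plan a [SegmentPlan-class] covering `nSnps(source)` columns.
#' @param nOut number of samples to generate.
#' @return an unlabeled [GenotypePanel-class] with `nOut` rows and the
#'   source's SNP ids.
#' @export
resamplePanel <- function(source, plan, nOut) {
  stopifnot(is(source, "GenotypePanel"), is(plan, "SegmentPlan"))
  if (plan@nSnps != ncol(source@genotypes))
    stop("segment plan does not cover the source panel's width")
  ns <- nrow(source@genotypes)
  if (ns < 1L) stop("source panel is empty")
  nOut <- as.integer(nOut)
  if (nOut < 1L) stop("nOut must be positive")
  out <- matrix(0L, nOut, plan@nSnps)
  bounds <- segmentBounds(plan)
  for (s in seq_len(nrow(bounds))) {
    rows <- sample.int(ns, nOut, replace = TRUE)
    cols <- bounds[s, 1L]:bounds[s, 2L]
    out[, cols] <- source@genotypes[rows, cols, drop = FALSE]
  }
  genotypePanel(out, snpIds = source@snpIds)
}

#' Full resampling pipeline: window, case removal, segmentation, splicing
#'
#' Convenience wrapper chaining [selectWindow()], [dropCases()] (when the
#' reference is labeled), [makeSegments()] and [resamplePanel()].
#'
#' @param reference a [GenotypePanel-class] reference panel.
#' @param nSnps number of SNPs the simulated panel should have.
#' @param nOut number of simulated samples.
#' @param nSegments segments to splice from; default one per 20 SNPs.
#' @param seed optional integer seed.
#' @return an unlabeled [GenotypePanel-class].
#' @examples
#' ref <- synthReferencePanel(200, 60, seed = 7)
#' sim <- simulatePanel(ref, nSnps = 40, nOut = 100, seed = 8)
#' @export
simulatePanel <- function(reference, nSnps, nOut,
                          nSegments = max(1L, nSnps %/% 20L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  win <- selectWindow(reference, nSnps)
  if (length(win@labels)) win <- dropCases(win)
  plan <- makeSegments(nSnps, nSegments)
  resamplePanel(win, plan, nOut)
}
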