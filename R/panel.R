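#' Create a genotype panel
#'
#' A `GenotypePanel` is a samples x SNPs matrix of genotypes coded
#' 1 = AA, 2 = Aa, 3 = aa, with optional per-sample 0/1 case-control labels
#' (0 = control, 1 = case) and unique SNP identifiers.
#'
#' @param genotypes numeric or integer matrix with entries in \{1, 2, 3\};
#'   rows are samples, columns SNPs.
#' @param labels optional vector of 0/1 labels, one per row.
#' @param snpIds optional character vector of SNP names; defaults to
#'   `"snp1"`, `"snp2"`, ...
#' @param object a `GenotypePanel` (accessor methods).
#' @return a validated [GenotypePanel-class].
#' @examples
#' p <- genotypePanel(matrix(c(1L, 2L, 3L, 1L), 2, 2), labels = c(0, 1))
#' nSamples(p); nSnps(p)
#' @export
genotypePanel <- function(genotypes, labels = NULL, snpIds = NULL) {
  g <- as.matrix(genotypes)
  storage.mode(g) <- "integer"
  dimnames(g) <- NULL
  if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(ncol(g)))
  new("GenotypePanel",
      genotypes = g,
      labels = if (is.null(labels)) integer() else as.integer(labels),
      snpIds = as.character(snpIds))
}

#' @rdname genotypePanel
#' @export
setMethod("genotypes", "GenotypePanel", function(object) object@genotypes)

#' @rdname genotypePanel
#' @export
setMethod("sampleLabels", "GenotypePanel", function(object)
  if (length(object@labels)) object@labels else NULL)

#' @rdname genotypePanel
#' @export
setMethod("snpIds", "GenotypePanel", function(object) object@snpIds)

#' @rdname genotypePanel
#' @export
setMethod("nSamples", "GenotypePanel", function(object) nrow(object@genotypes))

#' @rdname genotypePanel
#' @export
setMethod("nSnps", "GenotypePanel", function(object) ncol(object@genotypes))

#' @export
setMethod("show", "GenotypePanel", function(object) {
  cat(sprintf("GenotypePanel: %d samples x %d SNPs",
              nrow(object@genotypes), ncol(object@genotypes)))
  if (length(object@labels))
    cat(sprintf(" (%d cases / %d controls)",
                sum(object@labels == 1L), sum(object@labels == 0L)))
  else cat(" (unlabeled)")
  cat("\n")
  invisible(NULL)
})

#' Read and write genotype panels as delimited text
#'
#' Two dialects are supported.  `"labeled123"` (the default): each row is a
#' 0/1 label followed by genotypes coded \{1, 2, 3\}.  `"additive012"`:
#' no label column, genotypes in additive coding \{0, 1, 2\} (copies of the
#' rare allele), shifted to \{1, 2, 3\} on read and back on write.  Fields
#' may be separated by tabs, commas or spaces on read; tabs are written.
#' An optional header line of SNP identifiers is written and auto-detected
#' on read (any non-numeric first line).
#'
#' A panel survives `readPanel(writePanel(...))` exactly, and parse errors
#' (out-of-alphabet genotypes, ragged rows, non-0/1 labels) name the
#' offending line and column.
#'
#' @param path file path.
#' @param dialect `"labeled123"` or `"additive012"`.
#' @param panel a [GenotypePanel-class] to write.
#' @param header write / expect a SNP-id header line? Default `TRUE` for
#'   write; auto-detected on read.
#' @return `readPanel`: a [GenotypePanel-class]; `writePanel`: the path,
#'   invisibly.
#' @export
readPanel <- function(path, dialect = c("labeled123", "additive012")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("panel file is empty: ", path)
  toks <- strsplit(trimws(lines), "[\t, ]+")
  headerIds <- NULL
  if (anyNA(suppressWarnings(as.numeric(toks[[1L]])))) {
    headerIds <- toks[[1L]]
    toks <- toks[-1L]
    lineOffset <- 1L
  } else lineOffset <- 0L
  if (!length(toks)) stop("panel file has a header but no data rows: ", path)
  widths <- lengths(toks)
  if (length(unique(widths)) != 1L)
    stop(sprintf("ragged panel file: line %d has %d fields, expected %d",
                 which(widths != widths[1L])[1L] + lineOffset,
                 widths[which(widths != widths[1L])[1L]], widths[1L]))
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(toks)), nrow = length(toks), byrow = TRUE))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric field at line %d, column %d",
                 bad[1L, 1L] + lineOffset, bad[1L, 2L]))
  if (dialect == "labeled123") {
    if (ncol(vals) < 2L)
      stop("labeled123 panel needs a label column plus at least one SNP")
    labels <- vals[, 1L]
    bad <- which(!(labels %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("invalid label %g at line %d, column 1",
                   labels[bad[1L]], bad[1L] + lineOffset))
    g <- vals[, -1L, drop = FALSE]
    ids <- if (!is.null(headerIds)) headerIds[-1L] else NULL
    bad <- which(!(g %in% c(1, 2, 3)), arr.ind = FALSE)
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(g))
      stop(sprintf("invalid genotype %g at line %d, column %d (must be 1, 2 or 3)",
                   g[bad[1L]], rc[1L] + lineOffset, rc[2L] + 1L))
    }
    genotypePanel(g, labels = labels, snpIds = ids)
  } else {
    g <- vals
    bad <- which(!(g %in% c(0, 1, 2)), arr.ind = FALSE)
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(g))
      stop(sprintf("invalid additive genotype %g at line %d, column %d (must be 0, 1 or 2)",
                   g[bad[1L]], rc[1L] + lineOffset, rc[2L]))
    }
    genotypePanel(g + 1, snpIds = headerIds)
  }
}

#' @rdname readPanel
#' @export
writePanel <- function(panel, path, dialect = c("labeled123", "additive012"),
                       header = TRUE) {
  stopifnot(is(panel, "GenotypePanel"))
  dialect <- match.arg(dialect)
  g <- panel@genotypes
  if (dialect == "labeled123") {
    if (!length(panel@labels))
      stop("labeled123 dialect requires labels; use dialect = 'additive012'")
    body <- cbind(panel@labels, g)
    head <- c("label", panel@snpIds)
  } else {
    body <- g - 1L
    head <- panel@snpIds
  }
  lines <- apply(body, 1L, paste, collapse = "\t")
  if (header) lines <- c(paste(head, collapse = "\t"), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Extract a random window of consecutive SNPs
#'
#' Picks a uniformly random start column and returns the contiguous block
#' of `nSnps` columns from it; rows and labels are unchanged.  This is the
#' first step of resampling: the window width is the number of SNPs the
#' simulated data will have.
#'
#' @param panel a [GenotypePanel-class].
#' @param nSnps window width, at most `nSnps(panel)`.
#' @param start optional fixed start column (1-based); random if `NULL`.
#' @return a [GenotypePanel-class] with `nSnps` columns.
#' @export
selectWindow <- function(panel, nSnps, start = NULL) {
  stopifnot(is(panel, "GenotypePanel"))
  w <- ncol(panel@genotypes)
  if (nSnps < 1L || nSnps > w)
    stop(sprintf("window width must be in [1, %d]", w))
  if (is.null(start))
    start <- sample.int(w - nSnps + 1L, 1L)
  else if (start < 1L || start + nSnps - 1L > w)
    stop("window falls outside the panel")
  cols <- start:(start + nSnps - 1L)
  genotypePanel(panel@genotypes[, cols, drop = FALSE],
                labels = if (length(panel@labels)) panel@labels else NULL,
                snpIds = panel@snpIds[cols])
}

#' Drop case samples from a labeled panel
#'
#' Removes all samples labeled 1, keeping controls in their original order.
#' Removing the cases before resampling reduces the influence of whatever
#' disease model produced the reference panel on the simulated data.
#'
#' @param panel a labeled [GenotypePanel-class].
#' @return an all-control [GenotypePanel-class].
#' @export
dropCases <- function(panel) {
  stopifnot(is(panel, "GenotypePanel"))
  if (!length(panel@labels))
    stop("panel has no labels; cannot identify case samples")
  keep <- panel@labels == 0L
  if (!any(keep))
    stop("no control samples remain after removing cases")
  genotypePanel(panel@genotypes[keep, , drop = FALSE],
                labels = panel@labels[keep],
                snpIds = panel@snpIds)
}
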