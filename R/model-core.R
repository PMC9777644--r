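#' Create a model specification
#'
#' Builds a [ModelSpec-class] describing the eNME model to be solved: the
#' order K (taken from the number of MAFs), the per-SNP minor allele
#' frequencies, the target prevalence, and optionally the target
#' heritability.  When `heritability` is supplied the spec is in `"joint"`
#' mode (both prevalence and heritability are constrained, solved by Newton
#' iteration); otherwise it is in `"prevalence"` mode (linear constraints
#' only, solved by a minimum-norm decomposition).
#'
#' With `warn = TRUE` (the default) the constructor emits warnings, never
#' errors, when parameters fall outside the ranges for which model solving
#' has a high success rate: prevalence and heritability up to 0.3 for orders
#' 2 and 3 and up to 0.2 for order 4 and above, and MAFs between 0.05 and
#' 0.3.  Values outside those ranges are still accepted.
#'
#' @param mafs numeric vector of K minor allele frequencies, each in (0, 0.5].
#' @param prevalence target population prevalence, in (0, 1).
#' @param heritability optional target heritability, in (0, 1); supplying it
#'   switches the spec to joint mode.
#' @param warn emit recommended-range warnings? Default `TRUE`.
#' @return a validated [ModelSpec-class].
#' @examples
#' modelSpec(mafs = c(0.2, 0.2), prevalence = 0.1)
#' modelSpec(mafs = c(0.1, 0.3, 0.2), prevalence = 0.1, heritability = 0.05)
#' @export
modelSpec <- function(mafs, prevalence, heritability = NULL, warn = TRUE) {
  spec <- new("ModelSpec",
    K = length(mafs),
    mafs = as.numeric(mafs),
    prevalence = as.numeric(prevalence),
    heritability = if (is.null(heritability)) numeric() else
      as.numeric(heritability),
    mode = if (is.null(heritability)) "prevalence" else "joint"
  )
  if (warn) checkRecommendedRanges(spec)
  spec
}

#' Warn when a spec leaves the recommended parameter ranges
#'
#' Model solving succeeds most reliably for prevalence and heritability in
#' (0, 0.3] at orders 2-3 and (0, 0.2] at order 4 and above, with MAFs in
#' \[0.05, 0.3\].  Outside those ranges the solvers still run but may need
#' many restarts or fail to find an in-box solution.  This check never
#' errors; it only warns.
#'
#' @param spec a [ModelSpec-class].
#' @return `TRUE` (invisibly) if all parameters are inside the recommended
#'   ranges, `FALSE` otherwise.
#' @export
checkRecommendedRanges <- function(spec) {
  ok <- TRUE
  cap <- if (spec@K <= 3L) 0.3 else 0.2
  if (spec@prevalence > cap) {
    ok <- FALSE
    warning(sprintf(
      "prevalence %.3g exceeds the recommended maximum %.1f for order %d; solving may fail or need many restarts",
      spec@prevalence, cap, spec@K), call. = FALSE)
  }
  if (length(spec@heritability) && spec@heritability > cap) {
    ok <- FALSE
    warning(sprintf(
      "heritability %.3g exceeds the recommended maximum %.1f for order %d",
      spec@heritability, cap, spec@K), call. = FALSE)
  }
  if (any(spec@mafs < 0.05) || any(spec@mafs > 0.3)) {
    ok <- FALSE
    warning("MAFs outside [0.05, 0.3] reduce the solver success rate",
            call. = FALSE)
  }
  invisible(ok)
}

#' Create a penetrance table
#'
#' @param values numeric vector of 3^K penetrance values in \[0, 1\], in
#'   canonical cell order (SNP 1's genotype varies fastest; see
#'   [cellIndex()]).
#' @param mafs numeric vector of the K minor allele frequencies the table was
#'   solved or published under.
#' @param object a `PenetranceTable` (accessor methods).
#' @return a validated [PenetranceTable-class].
#' @examples
#' # a classic published two-locus model without marginal effects
#' tab <- penetranceTable(
#'   c(0.4865, 0.9601, 0.5377,
#'     0.9473, 0.0042, 0.8113,
#'     0.6401, 0.6065, 0.9089),
#'   mafs = c(0.2, 0.2))
#' prevalence(tab)     # ~0.64
#' heritability(tab)   # ~0.40
#' @export
penetranceTable <- function(values, mafs) {
  new("PenetranceTable",
    K = length(mafs),
    mafs = as.numeric(mafs),
    values = as.numeric(values))
}

#' @rdname penetranceTable
#' @export
setMethod("penetranceValues", "PenetranceTable", function(object) object@values)

#' @rdname penetranceTable
#' @export
setMethod("modelOrder", "PenetranceTable", function(object) object@K)

#' @rdname penetranceTable
#' @export
setMethod("modelMafs", "PenetranceTable", function(object) object@mafs)

#' @export
setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: order %d, mode '%s'\n", object@K, object@mode))
  cat("  MAFs:        ", paste(format(object@mafs), collapse = ", "), "\n")
  cat("  prevalence:  ", format(object@prevalence), "\n")
  if (length(object@heritability))
    cat("  heritability:", format(object@heritability), "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "PenetranceTable", function(object) {
  cat(sprintf("PenetranceTable: order %d (%d cells)\n",
              object@K, length(object@values)))
  cat("  MAFs:", paste(format(object@mafs), collapse = ", "), "\n")
  p <- prevalence(object)
  cat(sprintf("  prevalence %.4f", p))
  if (p > 0 && p < 1)
    cat(sprintf(", heritability %.4f", heritability(object)))
  cat("\n")
  if (object@K == 2L) {
    m <- matrix(object@values, 3, 3)  # rows: SNP1 genotype, cols: SNP2
    dimnames(m) <- list(SNP1 = c("AA", "Aa", "aa"), SNP2 = c("BB", "Bb", "bb"))
    print(round(m, 4))
  }
  invisible(NULL)
})

# ---- genotype-frequency arithmetic -----------------------------------------

#' Hardy-Weinberg genotype frequencies at a given minor allele frequency
#'
#' For minor allele frequency p, returns the genotype frequencies
#' ((1-p)^2, 2p(1-p), p^2) for (homozygous common, heterozygous, homozygous
#' rare), i.e. (AA, Aa, aa).
#'
#' @param maf minor allele frequency, in \[0, 0.5\].
#' @return numeric vector of 3 probabilities summing to 1, named
#'   `c("AA", "Aa", "aa")`.
#' @examples
#' genotypeFreqs(0.2)  # 0.64, 0.32, 0.04
#' @export
genotypeFreqs <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) ||
      maf < 0 || maf > 0.5)
    stop("maf must be a single number in [0, 0.5]")
  c(AA = (1 - maf)^2, Aa = 2 * maf * (1 - maf), aa = maf^2)
}

# Per-SNP genotype frequency matrix (K x 3) and joint cell frequencies
# (length 3^K) for a MAF vector; K = 1 is allowed here even though ModelSpec
# requires K >= 2, so the joint distribution degenerates gracefully.
jointFreqsFromMafs <- function(mafs) {
  K <- length(mafs)
  perSnp <- matrix(vapply(mafs, genotypeFreqs, numeric(3)),
                   nrow = K, byrow = TRUE,
                   dimnames = list(NULL, c("AA", "Aa", "aa")))
  joint <- perSnp[1L, ]
  for (k in seq_len(K)[-1L])      # SNP 1 varies fastest
    joint <- as.vector(outer(joint, perSnp[k, ]))
  list(perSnp = perSnp, joint = unname(joint))
}

#' Per-SNP and joint genotype frequencies of a model spec
#'
#' Computes, under Hardy-Weinberg equilibrium at each SNP and linkage
#' equilibrium between SNPs, the K x 3 matrix of per-SNP genotype
#' frequencies and the length-3^K vector of joint cell frequencies
#' P(g_i) = prod_k q_k\[digit_k(i)\], in canonical cell order.
#'
#' @param spec a [ModelSpec-class], or a bare numeric vector of MAFs.
#' @return a list with elements `perSnp` (K x 3 matrix, rows summing to 1)
#'   and `joint` (length 3^K, summing to 1).
#' @examples
#' f <- jointFreqs(modelSpec(c(0.2, 0.2), prevalence = 0.1))
#' f$joint[1]  # P(AA, BB) = 0.64 * 0.64 = 0.4096
#' @export
jointFreqs <- function(spec) {
  mafs <- if (is(spec, "ModelSpec")) spec@mafs else as.numeric(spec)
  jointFreqsFromMafs(mafs)
}

# ---- cell indexing ----------------------------------------------------------

#' Canonical cell indexing of a K-locus penetrance table
#'
#' The 3^K cells of a K-locus table are laid out in a fixed base-3 order:
#' the 1-based cell index of genotype digits (d_1, ..., d_K), each digit in
#' \{0, 1, 2\} (0 = homozygous common, 1 = heterozygous, 2 = homozygous
#' rare), is `1 + sum_k d_k * 3^(k-1)`, so SNP 1's genotype varies fastest.
#' For a 2-locus table this reads left-to-right, top-to-bottom across the
#' usual 3 x 3 layout (x1 = (AA, BB) ... x9 = (aa, bb)).
#'
#' @param digits integer vector of K genotype codes in \{0, 1, 2\}, or a
#'   matrix with one K-digit row per cell.
#' @param index 1-based cell index (vectorized).
#' @param K model order.
#' @return `cellIndex`: 1-based cell index (vector if `digits` is a matrix);
#'   `cellDigits`: integer vector of K digits, or a matrix with one row per
#'   index.
#' @examples
#' cellIndex(c(0, 0))  # 1: the (AA, BB) cell
#' cellIndex(c(2, 2))  # 9: the (aa, bb) cell
#' cellDigits(6, K = 2)  # c(2, 1): (aa, Bb)
#' @export
cellIndex <- function(digits) {
  if (is.matrix(digits)) {
    K <- ncol(digits)
    if (anyNA(digits) || any(digits < 0L) || any(digits > 2L))
      stop("genotype digits must be in {0, 1, 2}")
    return(as.integer(1L + digits %*% 3^(seq_len(K) - 1L)))
  }
  if (anyNA(digits) || any(digits < 0L) || any(digits > 2L))
    stop("genotype digits must be in {0, 1, 2}")
  as.integer(1L + sum(digits * 3^(seq_along(digits) - 1L)))
}

#' @rdname cellIndex
#' @export
cellDigits <- function(index, K) {
  if (anyNA(index) || any(index < 1L) || any(index > 3L^K))
    stop(sprintf("cell index must be in [1, %d]", 3L^K))
  i <- as.integer(index) - 1L
  d <- vapply(seq_len(K),
              function(k) as.integer((i %/% 3L^(k - 1L)) %% 3L),
              integer(length(i)))
  if (length(index) == 1L) as.integer(d) else matrix(as.integer(d), ncol = K)
}

# Digit matrix (3^K x K) of all cells in canonical order.
allCellDigits <- function(K) {
  cellDigits(seq_len(3L^K), K)
}

# ---- model statistics -------------------------------------------------------

#' @rdname prevalence
#' @export
setMethod("prevalence", "PenetranceTable", function(object, ...) {
  sum(object@values * jointFreqsFromMafs(object@mafs)$joint)
})

#' @rdname heritability
#' @export
setMethod("heritability", "PenetranceTable", function(object, ...) {
  pg <- jointFreqsFromMafs(object@mafs)$joint
  p <- sum(object@values * pg)
  if (p <= 0 || p >= 1)
    stop("heritability is undefined for a degenerate model (prevalence 0 or 1)")
  sum((object@values - p)^2 * pg) / (p * (1 - p))
})

#' Marginal penetrance of one SNP genotype
#'
#' The disease probability given a single SNP's genotype, averaging the
#' penetrance over the other K-1 SNPs' genotype distributions:
#' P(D|SNP k = j) = sum over cells i with digit_k(i) = j of
#' P(D|g_i) * prod_\{l != k\} q_l\[digit_l(i)\].
#' For a model without marginal effects, every marginal penetrance equals
#' the prevalence.
#'
#' @param table a [PenetranceTable-class].
#' @param snp SNP index in 1..K.
#' @param genotype genotype code 0 (homozygous common), 1 (heterozygous) or
#'   2 (homozygous rare).
#' @return a probability in \[0, 1\].
#' @examples
#' tab <- penetranceTable(
#'   c(0.4865, 0.9601, 0.5377, 0.9473, 0.0042, 0.8113,
#'     0.6401, 0.6065, 0.9089), mafs = c(0.2, 0.2))
#' marginalPenetrance(tab, snp = 1, genotype = 0)  # ~0.64 = prevalence
#' @export
marginalPenetrance <- function(table, snp, genotype) {
  stopifnot(is(table, "PenetranceTable"))
  K <- table@K
  if (length(snp) != 1L || is.na(snp) || snp < 1L || snp > K)
    stop(sprintf("snp must be in [1, %d]", K))
  if (length(genotype) != 1L || is.na(genotype) ||
      !(genotype %in% c(0L, 1L, 2L)))
    stop("genotype must be 0, 1 or 2")
  f <- jointFreqsFromMafs(table@mafs)
  digs <- allCellDigits(K)
  sel <- digs[, snp] == genotype
  # conditional weight of each selected cell: product of the OTHER SNPs'
  # genotype frequencies = joint / q_snp[genotype]
  qk <- f$perSnp[snp, genotype + 1L]
  if (qk == 0) {
    # frequency-zero stratum: average with the other SNPs' weights directly
    w <- rep(1, sum(sel))
    for (l in seq_len(K)) if (l != snp)
      w <- w * f$perSnp[l, digs[sel, l] + 1L]
    return(sum(table@values[sel] * w))
  }
  sum(table@values[sel] * f$joint[sel] / qk)
}

# All 3K marginal penetrances as a data.frame (snp, genotype, marginal).
allMarginals <- function(table) {
  K <- table@K
  grid <- expand.grid(genotype = 0:2, snp = seq_len(K))
  data.frame(
    snp = grid$snp,
    genotype = grid$genotype,
    marginal = mapply(function(s, g) marginalPenetrance(table, s, g),
                      grid$snp, grid$genotype)
  )
}

#' Check a penetrance table against its model specification
#'
#' Report-only check of the eNME contract: every single-SNP marginal
#' penetrance and the prevalence must equal the target prevalence, the
#' heritability must equal the target in joint mode, and all values must lie
#' in \[0, 1\].
#'
#' @param table a [PenetranceTable-class].
#' @param spec a [ModelSpec-class] with the same order and MAFs.
#' @param tol tolerance applied to every deviation. Default 1e-6.
#' @return a list with components `marginals` (data.frame of all 3K marginal
#'   penetrances and their deviations from the target), `maxMarginalDev`,
#'   `prevalenceDev`, `heritabilityDev` (NA in prevalence-only mode),
#'   `boxViolations` (count of out-of-\[0,1\] values) and `passes`.
#' @export
validateTable <- function(table, spec, tol = 1e-6) {
  stopifnot(is(table, "PenetranceTable"), is(spec, "ModelSpec"))
  if (table@K != spec@K || !isTRUE(all.equal(table@mafs, spec@mafs)))
    stop("table and spec must have the same order and MAFs")
  marg <- allMarginals(table)
  marg$deviation <- marg$marginal - spec@prevalence
  p <- prevalence(table)
  prevDev <- p - spec@prevalence
  h2Dev <- if (spec@mode == "joint")
    heritability(table) - spec@heritability else NA_real_
  box <- sum(table@values < -tol | table@values > 1 + tol)
  passes <- max(abs(marg$deviation)) <= tol &&
    abs(prevDev) <= tol &&
    (is.na(h2Dev) || abs(h2Dev) <= tol) &&
    box == 0L
  list(
    marginals = marg,
    maxMarginalDev = max(abs(marg$deviation)),
    prevalenceDev = prevDev,
    heritabilityDev = h2Dev,
    boxViolations = box,
    passes = passes
  )
}

# ---- penetrance-table file I/O ---------------------------------------------

#' Read and write penetrance-table files
#'
#' Plain-text format: header lines `K`, `mafs`, `prevalence`, `heritability`
#' (tab-separated key and value(s); prevalence and heritability are
#' informational, recomputed on read), followed by 3^K lines
#' `d_1,...,d_K<TAB>value` in canonical cell order.  Values are written with
#' 17 significant digits so that the decimal strings round-trip exactly.
#'
#' @param path file path.
#' @param table a [PenetranceTable-class] to write.
#' @return `readPenetranceTable`: a [PenetranceTable-class];
#'   `writePenetranceTable`: the path, invisibly.
#' @export
readPenetranceTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(fields, `[[`, character(1), 1L)
  getHeader <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) return(NULL)
    as.numeric(fields[[i]][-1L])
  }
  K <- getHeader("K")
  mafs <- getHeader("mafs")
  if (is.null(K) || is.null(mafs))
    stop("penetrance-table file must have 'K' and 'mafs' header lines")
  K <- as.integer(K)
  body <- fields[!(keys %in% c("K", "mafs", "prevalence", "heritability"))]
  if (length(body) != 3L^K)
    stop(sprintf("expected %d cell lines, found %d", 3L^K, length(body)))
  values <- numeric(3L^K)
  for (ln in body) {
    if (length(ln) != 2L)
      stop("each cell line must be 'digits<TAB>value'")
    digits <- as.integer(strsplit(ln[[1L]], ",", fixed = TRUE)[[1L]])
    if (length(digits) != K)
      stop(sprintf("cell '%s' does not have %d digits", ln[[1L]], K))
    values[cellIndex(digits)] <- as.numeric(ln[[2L]])
  }
  penetranceTable(values, mafs)
}

#' @rdname readPenetranceTable
#' @export
writePenetranceTable <- function(table, path) {
  stopifnot(is(table, "PenetranceTable"))
  fmt <- function(x) sprintf("%.17g", x)
  p <- prevalence(table)
  lines <- c(
    paste0("K\t", table@K),
    paste0("mafs\t", paste(fmt(table@mafs), collapse = "\t")),
    paste0("prevalence\t", fmt(p)),
    if (p > 0 && p < 1)
      paste0("heritability\t", fmt(heritability(table)))
  )
  digs <- allCellDigits(table@K)
  lines <- c(lines, paste0(
    apply(digs, 1L, paste, collapse = ","), "\t", fmt(table@values)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a model specification from a key-value config file
#'
#' Accepts lines of the form `key = value` (or `key: value`); recognized
#' keys are `mafs` (comma-separated), `prevalence`, `heritability`
#' (optional) and `seed` (optional, returned as an attribute).  `order`, if
#' present, must agree with the number of MAFs.
#'
#' @param path config file path.
#' @param warn passed to [modelSpec()].
#' @return a [ModelSpec-class]; a `seed` key, if present, is attached as
#'   attribute `"seed"`.
#' @export
readModelConfig <- function(path, warn = TRUE) {
  kv <- readKeyValueFile(path)
  if (is.null(kv$mafs) || is.null(kv$prevalence))
    stop("config must define 'mafs' and 'prevalence'")
  mafs <- as.numeric(strsplit(kv$mafs, ",", fixed = TRUE)[[1L]])
  if (!is.null(kv$order) && as.integer(kv$order) != length(mafs))
    stop("config 'order' disagrees with the number of MAFs")
  spec <- modelSpec(mafs, as.numeric(kv$prevalence),
                    heritability = if (is.null(kv$heritability)) NULL else
                      as.numeric(kv$heritability),
                    warn = warn)
  if (!is.null(kv$seed)) attr(spec, "seed") <- as.integer(kv$seed)
  spec
}

# key = value / key: value file -> named list of character values
readKeyValueFile <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*[=:]\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("cannot parse config line: '%s'", ln))
    kv[[m[2L]]] <- trimws(m[3L])
  }
  kv
}
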