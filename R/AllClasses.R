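#' @import methods
NULL

#' Specification of an eNME epistasis model to be solved
#'
#' A `ModelSpec` bundles the user's request for a K-order epistasis model
#' without marginal effects: the per-SNP minor allele frequencies, the target
#' population prevalence, and (in joint mode) the target heritability.
#'
#' @slot K integer; model order (number of interacting SNPs), at least 2.
#' @slot mafs numeric vector of length `K`; minor allele frequencies, each in
#'   (0, 0.5].
#' @slot prevalence numeric; target population prevalence P(D), in (0, 1).
#' @slot heritability numeric; target heritability h-squared, in (0, 1), or
#'   length 0 when only prevalence is constrained.
#' @slot mode character; `"prevalence"` or `"joint"`, always consistent with
#'   whether `heritability` is present.
#'
#' @seealso [modelSpec()] for the user-facing constructor.
#' @export
setClass("ModelSpec",
  representation(
    K = "integer",
    mafs = "numeric",
    prevalence = "numeric",
    heritability = "numeric",
    mode = "character"
  )
)

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (length(object@K) != 1L || is.na(object@K) || object@K < 2L)
    msg <- c(msg, "K must be a single integer >= 2")
  if (length(object@mafs) != object@K)
    msg <- c(msg, "length(mafs) must equal K")
  if (any(is.na(object@mafs)) || any(object@mafs <= 0) || any(object@mafs > 0.5))
    msg <- c(msg, "every MAF must lie in (0, 0.5]")
  if (length(object@prevalence) != 1L || is.na(object@prevalence) ||
      object@prevalence <= 0 || object@prevalence >= 1)
    msg <- c(msg, "prevalence must lie in (0, 1)")
  if (length(object@heritability) > 1L)
    msg <- c(msg, "heritability must be absent or a single number")
  if (length(object@heritability) == 1L &&
      (is.na(object@heritability) || object@heritability < 0 ||
       object@heritability >= 1))
    msg <- c(msg, "heritability must lie in [0, 1)")
  if (!identical(object@mode, "prevalence") && !identical(object@mode, "joint"))
    msg <- c(msg, "mode must be 'prevalence' or 'joint'")
  if (identical(object@mode, "joint") != (length(object@heritability) == 1L))
    msg <- c(msg, "mode is 'joint' if and only if heritability is present")
  if (length(msg)) msg else TRUE
})

#' Penetrance table of a K-order epistasis model
#'
#' Holds the 3^K penetrance values P(D|g_i) of a K-locus model together with
#' the minor allele frequencies under which they were solved (or published).
#' Cells are stored in a fixed canonical order: the base-3 expansion of the
#' 0-based cell index with SNP 1 as the least-significant digit (SNP 1's
#' genotype varies fastest), genotype codes 0 = homozygous common, 1 =
#' heterozygous, 2 = homozygous rare.  See [cellIndex()].
#'
#' @slot K integer; model order.
#' @slot mafs numeric; minor allele frequencies of the K SNPs.
#' @slot values numeric vector of length 3^K; penetrance values, each in
#'   \[0, 1\], in canonical cell order.
#'
#' @seealso [penetranceTable()], [prevalence()], [heritability()],
#'   [marginalPenetrance()], [validateTable()].
#' @export
setClass("PenetranceTable",
  representation(
    K = "integer",
    mafs = "numeric",
    values = "numeric"
  )
)

setValidity("PenetranceTable", function(object) {
  msg <- character()
  if (length(object@K) != 1L || is.na(object@K) || object@K < 1L)
    msg <- c(msg, "K must be a single positive integer")
  if (length(object@mafs) != object@K)
    msg <- c(msg, "length(mafs) must equal K")
  if (any(is.na(object@mafs)) || any(object@mafs < 0) || any(object@mafs > 0.5))
    msg <- c(msg, "every MAF must lie in [0, 0.5]")
  if (length(object@values) != 3L^object@K)
    msg <- c(msg, sprintf("values must have length 3^K = %d", 3L^object@K))
  if (any(is.na(object@values)) || any(object@values < 0) ||
      any(object@values > 1))
    msg <- c(msg, "all penetrance values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Linear constraint system of a prevalence-constrained eNME model
#'
#' Encodes the marginal-penetrance and prevalence constraints on the 3^K
#' unknown penetrance values as `A x = b` with `m = 3K + 1` rows (3K marginal
#' constraints plus one prevalence constraint) and `n = 3^K` columns.  Rows
#' are in conditional-frequency form: the coefficients of a marginal row are
#' the conditional cell frequencies given the fixed single-SNP genotype, so
#' every row sums to 1 and every entry of `b` equals the target prevalence.
#'
#' @slot A numeric matrix, `(3K+1) x 3^K`, nonnegative with unit row sums.
#' @slot b numeric right-hand side of length `3K + 1`.
#' @slot spec the [ModelSpec-class] the system was built from.
#'
#' @seealso [buildLinearSystem()], [codFactor()].
#' @export
setClass("LinearSystem",
  representation(
    A = "matrix",
    b = "numeric",
    spec = "ModelSpec"
  )
)

setValidity("LinearSystem", function(object) {
  msg <- character()
  if (nrow(object@A) != length(object@b))
    msg <- c(msg, "nrow(A) must equal length(b)")
  if (any(object@A < -1e-12))
    msg <- c(msg, "A must be nonnegative")
  if (any(abs(rowSums(object@A) - 1) > 1e-9))
    msg <- c(msg, "every row of A must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Complete orthogonal decomposition of a matrix
#'
#' Rank-revealing factorization `A P = Q [T 0; 0 0] Z'` with `Q` (m x m) and
#' `Z` (n x n) orthogonal, `P` a column permutation and `T` an r x r
#' triangular block with nonzero diagonal, r the numerical rank.  Built from
#' two LAPACK QR factorizations (a column-pivoted QR of `A`, then a QR of the
#' transposed leading rows); with this construction `T` comes out
#' lower-triangular.
#'
#' @slot Q numeric m x m orthogonal matrix.
#' @slot Z numeric n x n orthogonal matrix.
#' @slot R11 numeric r x r lower-triangular block with nonzero diagonal.
#' @slot pivot integer column permutation of A (as indices).
#' @slot rank integer numerical rank r.
#'
#' @seealso [codFactor()], [codSolve()], [nullSpaceBasis()].
#' @export
setClass("CODFactorization",
  representation(
    Q = "matrix",
    Z = "matrix",
    R11 = "matrix",
    pivot = "integer",
    rank = "integer"
  )
)

setValidity("CODFactorization", function(object) {
  msg <- character()
  r <- object@rank
  if (length(r) != 1L || is.na(r) || r < 0L)
    msg <- c(msg, "rank must be a single nonnegative integer")
  if (nrow(object@R11) != r || ncol(object@R11) != r)
    msg <- c(msg, "R11 must be rank x rank")
  if (length(object@pivot) != ncol(object@Z))
    msg <- c(msg, "pivot must have one entry per column of A")
  if (r > 0L && any(abs(diag(object@R11)) == 0))
    msg <- c(msg, "R11 must have nonzero diagonal")
  if (length(msg)) msg else TRUE
})

#' Result of solving for an eNME penetrance table
#'
#' A solved [PenetranceTable-class] plus solver diagnostics.
#'
#' @slot table the solved [PenetranceTable-class].
#' @slot residualNorm numeric; 2-norm of the constraint residual at the
#'   returned table (for the joint solver, the max-norm of the full nonlinear
#'   residual is also below the convergence tolerance).
#' @slot achievedHeritability numeric; heritability of the returned table.
#' @slot attempts integer; number of feasibility restarts used (1 = first
#'   attempt succeeded).
#' @slot iterations integer; Newton iterations of the successful attempt
#'   (0 for the linear, prevalence-only solver).
#' @slot seed integer; seed the solve was run under, or NA if none was set.
#'
#' @export
setClass("SolverResult",
  representation(
    table = "PenetranceTable",
    residualNorm = "numeric",
    achievedHeritability = "numeric",
    attempts = "integer",
    iterations = "integer",
    seed = "integer"
  )
)

setValidity("SolverResult", function(object) {
  msg <- character()
  if (object@residualNorm < 0) msg <- c(msg, "residualNorm must be >= 0")
  if (object@achievedHeritability < -1e-12)
    msg <- c(msg, "achievedHeritability must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A sample-by-SNP genotype panel
#'
#' Genotypes are coded 1 = AA (homozygous common), 2 = Aa (heterozygous),
#' 3 = aa (homozygous rare).  Labels, when present, code 0 = control,
#' 1 = case.
#'
#' @slot genotypes integer matrix, samples in rows, SNPs in columns, entries
#'   in \{1, 2, 3\}.
#' @slot labels integer vector of per-sample 0/1 labels, or length 0 when the
#'   panel is unlabeled.
#' @slot snpIds character vector of unique SNP identifiers, one per column.
#'
#' @seealso [genotypePanel()], [readPanel()], [writePanel()],
#'   [synthReferencePanel()].
#' @export
setClass("GenotypePanel",
  representation(
    genotypes = "matrix",
    labels = "integer",
    snpIds = "character"
  )
)

setValidity("GenotypePanel", function(object) {
  msg <- character()
  g <- object@genotypes
  if (!is.integer(g))
    msg <- c(msg, "genotypes must be an integer matrix")
  else if (anyNA(g) || any(g < 1L) || any(g > 3L))
    msg <- c(msg, "all genotype entries must be in {1, 2, 3}")
  if (length(object@labels) &&
      (length(object@labels) != nrow(g) ||
       anyNA(object@labels) || !all(object@labels %in% c(0L, 1L))))
    msg <- c(msg, "labels must be one 0/1 value per sample")
  if (length(object@snpIds) != ncol(g))
    msg <- c(msg, "snpIds must have one entry per SNP column")
  if (anyDuplicated(object@snpIds))
    msg <- c(msg, "snpIds must be unique")
  if (length(msg)) msg else TRUE
})

#' A contiguous column segmentation of a genotype panel
#'
#' Partitions columns 1..nSnps into contiguous, non-empty, disjoint segments
#' that cover every column exactly once, stored as the sorted 1-based start
#' column of each segment (the first start is always 1).
#'
#' @slot starts integer vector of segment start columns, strictly increasing,
#'   first element 1.
#' @slot nSnps integer; total number of columns partitioned.
#'
#' @seealso [makeSegments()], [resamplePanel()].
#' @export
setClass("SegmentPlan",
  representation(
    starts = "integer",
    nSnps = "integer"
  )
)

setValidity("SegmentPlan", function(object) {
  msg <- character()
  s <- object@starts
  if (length(s) < 1L || s[1L] != 1L)
    msg <- c(msg, "first segment must start at column 1")
  if (any(diff(s) < 1L))
    msg <- c(msg, "segment starts must be strictly increasing")
  if (length(s) && s[length(s)] > object@nSnps)
    msg <- c(msg, "segment starts must not exceed nSnps")
  if (length(msg)) msg else TRUE
})

#' Plan for embedding a solved model into a simulated panel
#'
#' Names the K panel columns that carry the model, the penetrance table to
#' embed, and the target case/control counts of the final dataset.
#'
#' @slot loci integer vector of K distinct column indices.
#' @slot table the [PenetranceTable-class] to embed.
#' @slot nCases integer; target number of case samples.
#' @slot nControls integer; target number of control samples.
#'
#' @seealso [embeddingPlan()], [generateCaseControl()], [selectModelLoci()].
#' @export
setClass("EmbeddingPlan",
  representation(
    loci = "integer",
    table = "PenetranceTable",
    nCases = "integer",
    nControls = "integer"
  )
)

setValidity("EmbeddingPlan", function(object) {
  msg <- character()
  if (anyDuplicated(object@loci))
    msg <- c(msg, "loci must be distinct")
  if (length(object@loci) != object@table@K)
    msg <- c(msg, "length(loci) must equal the table's order K")
  if (any(object@loci < 1L))
    msg <- c(msg, "loci must be positive column indices")
  if (object@nCases < 0L || object@nControls < 0L)
    msg <- c(msg, "case/control counts must be nonnegative")
  if (object@nCases + object@nControls < 1L)
    msg <- c(msg, "at least one sample must be requested")
  if (length(msg)) msg else TRUE
})
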