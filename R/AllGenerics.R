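#' Population prevalence of a penetrance table
#'
#' The frequency-weighted mean penetrance: P(D) = sum_i P(D|g_i) P(g_i),
#' with joint cell frequencies P(g_i) computed from the table's MAFs under
#' Hardy-Weinberg equilibrium and linkage equilibrium between the model SNPs.
#'
#' @param object a [PenetranceTable-class].
#' @param ... unused.
#' @return a probability in \[0, 1\].
#' @examples
#' tab <- penetranceTable(rep(0.3, 9), mafs = c(0.2, 0.2))
#' prevalence(tab)  # 0.3: constant tables have prevalence equal to the constant
#' @export
setGeneric("prevalence", function(object, ...) standardGeneric("prevalence"))

#' Heritability of a penetrance table
#'
#' The proportion of phenotypic variance attributable to the model:
#' h^2 = sum_i (P(D|g_i) - P(D))^2 P(g_i) / (P(D) (1 - P(D))).
#' Degenerate tables whose prevalence is exactly 0 or 1 have an undefined
#' heritability (the denominator vanishes) and raise an error.
#'
#' @param object a [PenetranceTable-class].
#' @param ... unused.
#' @return a nonnegative number; 0 for any constant table.
#' @export
setGeneric("heritability", function(object, ...) standardGeneric("heritability"))

#' @rdname penetranceTable
#' @export
setGeneric("penetranceValues", function(object) standardGeneric("penetranceValues"))

#' @rdname penetranceTable
#' @export
setGeneric("modelOrder", function(object) standardGeneric("modelOrder"))

#' @rdname penetranceTable
#' @export
setGeneric("modelMafs", function(object) standardGeneric("modelMafs"))

#' @rdname genotypePanel
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))

#' @rdname genotypePanel
#' @export
setGeneric("sampleLabels", function(object) standardGeneric("sampleLabels"))

#' @rdname genotypePanel
#' @export
setGeneric("snpIds", function(object) standardGeneric("snpIds"))

#' @rdname genotypePanel
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname genotypePanel
#' @export
setGeneric("nSnps", function(object) standardGeneric("nSnps"))

#' @rdname makeSegments
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))

#' @rdname makeSegments
#' @export
setGeneric("segmentBounds", function(object) standardGeneric("segmentBounds"))

#' @rdname solvePrevalenceModel
#' @export
setGeneric("solverTable", function(object) standardGeneric("solverTable"))
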