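#' @include AllGenerics.R
NULL

.checkDimnames <- function(m, what) {
    msgs <- character(0)
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return(sprintf("%s must have row and column names", what))
    if (anyDuplicated(rownames(m)))
        msgs <- c(msgs, sprintf("duplicated feature ids in %s: %s", what,
            paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")))
    if (anyDuplicated(colnames(m)))
        msgs <- c(msgs, sprintf("duplicated sample ids in %s", what))
    msgs
}

#' Longitudinal gene-expression matrix (FPKM)
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] holding one assay,
#' `"fpkm"`, with genes in rows and timepoints (samples) in columns.
#' Values are non-negative FPKM; missing cells are not allowed — the
#' within-individual time-course design assumes complete data at every
#' timepoint.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [ExpressionMatrix()], [readExpressionMatrix()]
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
    if (!"fpkm" %in% SummarizedExperiment::assayNames(object))
        return("assay 'fpkm' is required")
    m <- SummarizedExperiment::assay(object, "fpkm")
    msgs <- .checkDimnames(m, "expression matrix")
    if (!is.numeric(m))
        msgs <- c(msgs, "FPKM values must be numeric")
    else {
        if (anyNA(m))
            msgs <- c(msgs, "missing FPKM values are not allowed")
        else if (any(m < 0)) {
            bad <- which(m < 0, arr.ind = TRUE)[1L, ]
            msgs <- c(msgs, sprintf("negative FPKM at gene '%s', sample '%s'",
                rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values Numeric matrix of non-negative FPKM values with unique
#'   row (gene) and column (sample) names.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(c(0, 1.5, 3, 0), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("Day1", "Day2")))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values) {
    values <- as.matrix(values)
    se <- SummarizedExperiment::SummarizedExperiment(assays = list(fpkm = values))
    new("ExpressionMatrix", se)
}

#' Longitudinal DNA-methylation matrix (beta values)
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] holding one assay,
#' `"beta"`, with CpG probes in rows and timepoints in columns. Beta is the
#' ratio of methylated probe intensity to total signal intensity and lies
#' in \[0, 1\].
#'
#' @seealso [MethylationMatrix()], [readMethylationMatrix()]
#' @export
setClass("MethylationMatrix", contains = "SummarizedExperiment")

setValidity("MethylationMatrix", function(object) {
    if (!"beta" %in% SummarizedExperiment::assayNames(object))
        return("assay 'beta' is required")
    m <- SummarizedExperiment::assay(object, "beta")
    msgs <- .checkDimnames(m, "methylation matrix")
    if (!is.numeric(m))
        msgs <- c(msgs, "beta values must be numeric")
    else {
        if (anyNA(m))
            msgs <- c(msgs, "missing beta values are not allowed")
        else if (any(m < 0) || any(m > 1)) {
            bad <- which(m < 0 | m > 1, arr.ind = TRUE)[1L, ]
            msgs <- c(msgs, sprintf("beta outside [0,1] at probe '%s', sample '%s'",
                rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a MethylationMatrix
#'
#' @param values Numeric matrix of beta values in \[0, 1\] with unique row
#'   (probe) and column (sample) names.
#' @return A [MethylationMatrix-class] object.
#' @export
MethylationMatrix <- function(values) {
    values <- as.matrix(values)
    se <- SummarizedExperiment::SummarizedExperiment(assays = list(beta = values))
    new("MethylationMatrix", se)
}

#' Per-sample cell-type composition
#'
#' Estimated (or simulated true) cell-type proportions, samples in rows and
#' cell types in columns. Proportions are non-negative; the raw non-negative
#' least-squares projection need not sum exactly to one per sample, so the
#' sum constraint is a QC check ([compositionQC()]) rather than a validity
#' condition.
#'
#' @slot proportions Numeric matrix, samples x cell types, with dimnames.
#' @seealso [estimateComposition()], [simulateComposition()]
#' @export
setClass("CompositionMatrix", representation(proportions = "matrix"))

setValidity("CompositionMatrix", function(object) {
    m <- object@proportions
    msgs <- character(0)
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("proportions must have sample row names and cell-type column names")
    if (anyDuplicated(rownames(m))) msgs <- c(msgs, "duplicated sample ids")
    if (anyDuplicated(colnames(m))) msgs <- c(msgs, "duplicated cell-type labels")
    if (anyNA(m)) msgs <- c(msgs, "missing proportions are not allowed")
    else if (any(m < -1e-12)) msgs <- c(msgs, "negative proportions are not allowed")
    if (length(msgs)) msgs else TRUE
})

#' Construct a CompositionMatrix
#'
#' @param proportions Numeric matrix, samples in rows and cell types in
#'   columns, all entries non-negative.
#' @return A [CompositionMatrix-class] object.
#' @export
CompositionMatrix <- function(proportions) {
    new("CompositionMatrix", proportions = as.matrix(proportions))
}

#' Reference methylation signature
#'
#' Mean beta values of cell-type-discriminating CpG probes in purified cell
#' populations: probes in rows, cell types in columns. Used as the design
#' matrix of the constrained-projection deconvolution. The probe rows must
#' span the cell-type space (matrix rank equal to the number of cell
#' types), otherwise proportions are not identifiable.
#'
#' @slot values Numeric matrix in \[0, 1\], probes x cell types.
#' @seealso [estimateComposition()], [readSignature()]
#' @export
setClass("ReferenceSignature", representation(values = "matrix"))

setValidity("ReferenceSignature", function(object) {
    m <- object@values
    msgs <- character(0)
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("signature must have probe row names and cell-type column names")
    if (ncol(m) < 2) msgs <- c(msgs, "at least 2 cell types are required")
    if (anyDuplicated(rownames(m))) msgs <- c(msgs, "duplicated probe ids")
    if (anyNA(m) || any(m < 0) || any(m > 1))
        msgs <- c(msgs, "signature betas must lie in [0,1] with no missing values")
    else if (nrow(m) < ncol(m) || qr(m)$rank < ncol(m))
        msgs <- c(msgs, "signature probe rows do not span the cell types (rank-deficient)")
    if (length(msgs)) msgs else TRUE
})

#' Construct a ReferenceSignature
#'
#' @param values Numeric matrix of mean beta values in \[0, 1\], signature
#'   probes in rows and cell types in columns, full column rank.
#' @return A [ReferenceSignature-class] object.
#' @export
ReferenceSignature <- function(values) {
    new("ReferenceSignature", values = as.matrix(values))
}

## -- accessors -------------------------------------------------------------

#' @rdname fpkm
#' @export
setMethod("fpkm", "ExpressionMatrix", function(x)
    SummarizedExperiment::assay(x, "fpkm"))

#' @rdname betaValues
#' @export
setMethod("betaValues", "MethylationMatrix", function(x)
    SummarizedExperiment::assay(x, "beta"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname probeIds
#' @export
setMethod("probeIds", "MethylationMatrix", function(x) rownames(x))

#' @rdname probeIds
#' @export
setMethod("probeIds", "ReferenceSignature", function(x) rownames(x@values))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "MethylationMatrix", function(x) colnames(x))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "CompositionMatrix", function(x) rownames(x@proportions))

#' @rdname cellTypes
#' @export
setMethod("cellTypes", "CompositionMatrix", function(x) colnames(x@proportions))

#' @rdname cellTypes
#' @export
setMethod("cellTypes", "ReferenceSignature", function(x) colnames(x@values))

#' @rdname proportions
#' @export
setMethod("proportions", "CompositionMatrix", function(x) x@proportions)

## -- show ------------------------------------------------------------------

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix: %d genes x %d timepoints (FPKM)\n",
        nrow(object), ncol(object)))
    callNextMethod()
})

setMethod("show", "MethylationMatrix", function(object) {
    cat(sprintf("MethylationMatrix: %d CpG probes x %d timepoints (beta)\n",
        nrow(object), ncol(object)))
    callNextMethod()
})

setMethod("show", "CompositionMatrix", function(object) {
    p <- object@proportions
    cat(sprintf("CompositionMatrix: %d samples x %d cell types\n",
        nrow(p), ncol(p)))
    cat("  cell types:", paste(colnames(p), collapse = ", "), "\n")
    cat(sprintf("  per-sample sums: %.3f - %.3f\n",
        min(rowSums(p)), max(rowSums(p))))
})

setMethod("show", "ReferenceSignature", function(object) {
    m <- object@values
    cat(sprintf("ReferenceSignature: %d signature CpGs x %d cell types\n",
        nrow(m), ncol(m)))
    cat("  cell types:", paste(colnames(m), collapse = ", "), "\n")
})
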