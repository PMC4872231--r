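#' @import methods
NULL

#' Extract the FPKM assay
#'
#' @param x An [ExpressionMatrix-class] object.
#' @return Numeric matrix of FPKM values, genes in rows, timepoints in columns.
#' @export
setGeneric("fpkm", function(x) standardGeneric("fpkm"))

#' Extract the beta-value assay
#'
#' @param x A [MethylationMatrix-class] object.
#' @return Numeric matrix of beta values in \[0, 1\], probes in rows,
#'   timepoints in columns.
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' Gene identifiers
#' @param x An [ExpressionMatrix-class] object.
#' @return Character vector of gene ids in matrix order.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Probe identifiers
#' @param x A [MethylationMatrix-class] or [ReferenceSignature-class] object.
#' @return Character vector of CpG probe ids in matrix order.
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' Sample (timepoint) identifiers
#' @param x A methdyn matrix object.
#' @return Character vector of sample ids in matrix order.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Cell-type labels
#' @param x A [CompositionMatrix-class] or [ReferenceSignature-class] object.
#' @return Character vector of cell-type labels.
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' Estimated cell-type proportions
#' @param x A [CompositionMatrix-class] object.
#' @return Numeric matrix, samples in rows, cell types in columns.
#' @export
setGeneric("proportions", function(x) standardGeneric("proportions"))
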