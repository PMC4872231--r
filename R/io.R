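## TSV readers/writers for every matrix and annotation format, plus the QC
## filters shared by all stages. Dialect: UTF-8 tab-separated text, header
## row of sample ids, first column of feature ids; missing values are an
## error (the 24/24 complete time-course design assumes no holes).

.readMatrixTSV <- function(path, what, id_col) {
    if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
    df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                            colClasses = "character", quote = "")
    if (ncol(df) < 2) stop(what, " file needs an id column and >= 1 sample", call. = FALSE)
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop(sprintf("duplicate %s in %s: %s", id_col, path,
             paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
    body <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(num <- matrix(as.numeric(body), nrow(body), ncol(body)))
    if (anyNA(num)) {
        bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric or missing value in %s at %s '%s', sample '%s'",
             what, id_col, ids[bad[1L]], colnames(df)[-1L][bad[2L]]), call. = FALSE)
    }
    dimnames(num) <- list(ids, colnames(df)[-1L])
    num
}

.writeMatrixTSV <- function(m, path, id_col) {
    df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df)[1L] <- id_col
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    invisible(path)
}

#' Read / write an expression matrix
#'
#' Tab-separated text, sample ids in the header row, gene ids in the first
#' column, non-negative FPKM values in the body. Row and column order are
#' preserved. Negative, missing or non-numeric values and duplicated ids
#' are format errors naming the offending gene and sample.
#'
#' @param path Path to a TSV file.
#' @return `readExpressionMatrix`: an [ExpressionMatrix-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(c(0, 1.5, 3, 0), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("Day1", "Day2")))
#' writeExpressionMatrix(ExpressionMatrix(m), f)
#' fpkm(readExpressionMatrix(f))
#' @export
readExpressionMatrix <- function(path) {
    m <- .readMatrixTSV(path, "expression matrix", "gene id")
    if (any(m < 0)) {
        bad <- which(m < 0, arr.ind = TRUE)[1L, ]
        stop(sprintf("negative FPKM at gene '%s', sample '%s' in %s",
             rownames(m)[bad[1L]], colnames(m)[bad[2L]], path), call. = FALSE)
    }
    ExpressionMatrix(m)
}

#' @rdname readExpressionMatrix
#' @param x The object to write.
#' @return `writeExpressionMatrix`: the path, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
    stopifnot(is(x, "ExpressionMatrix"))
    .writeMatrixTSV(fpkm(x), path, "gene_id")
}

#' Read / write a methylation beta-value matrix
#'
#' Same dialect as [readExpressionMatrix()], CpG probe ids in the first
#' column, beta values in \[0, 1\] in the body.
#'
#' @param path Path to a TSV file.
#' @return `readMethylationMatrix`: a [MethylationMatrix-class].
#' @export
readMethylationMatrix <- function(path) {
    m <- .readMatrixTSV(path, "methylation matrix", "probe id")
    MethylationMatrix(m)
}

#' @rdname readMethylationMatrix
#' @param x The object to write.
#' @export
writeMethylationMatrix <- function(x, path) {
    stopifnot(is(x, "MethylationMatrix"))
    .writeMatrixTSV(betaValues(x), path, "probe_id")
}

#' Read / write a composition matrix (samples x cell types)
#' @param path Path to a TSV file (first column sample id).
#' @return `readCompositionMatrix`: a [CompositionMatrix-class].
#' @export
readCompositionMatrix <- function(path) {
    CompositionMatrix(.readMatrixTSV(path, "composition matrix", "sample id"))
}

#' @rdname readCompositionMatrix
#' @param x The object to write.
#' @export
writeCompositionMatrix <- function(x, path) {
    stopifnot(is(x, "CompositionMatrix"))
    .writeMatrixTSV(proportions(x), path, "sample_id")
}

#' Read / write a reference methylation signature (probes x cell types)
#' @param path Path to a TSV file (first column probe id).
#' @return `readSignature`: a [ReferenceSignature-class].
#' @export
readSignature <- function(path) {
    ReferenceSignature(.readMatrixTSV(path, "reference signature", "probe id"))
}

#' @rdname readSignature
#' @param x The object to write.
#' @export
writeSignature <- function(x, path) {
    stopifnot(is(x, "ReferenceSignature"))
    .writeMatrixTSV(x@values, path, "probe_id")
}

#' Read a per-probe detection p-value matrix
#'
#' Probes x samples matrix of array detection p-values, used by
#' [filterProbes()].
#' @param path Path to a TSV file (first column probe id).
#' @return Numeric matrix with probe row names and sample column names.
#' @export
readDetectionP <- function(path) .readMatrixTSV(path, "detection p-values", "probe id")

#' Read / write gene and CpG annotations
#'
#' BED-like tab-separated tables with a header. Gene annotation columns:
#' `gene_id`, `chromosome`, `tss` (1-based transcription start site),
#' `strand` (`+`/`-`). CpG annotation columns: `probe_id`, `chromosome`,
#' `position` (1-based), `snp_overlap` (0/1 flag marking probes that
#' coincide with known SNPs and are excluded from pairing).
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with the columns above.
#' @export
readGeneAnnotation <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE, quote = "")
    need <- c("gene_id", "chromosome", "tss", "strand")
    if (!all(need %in% colnames(df)))
        stop("gene annotation needs columns: ", paste(need, collapse = ", "),
             call. = FALSE)
    df$tss <- as.integer(df$tss)
    if (anyDuplicated(df$gene_id)) stop("duplicated gene_id in annotation", call. = FALSE)
    if (any(df$tss < 1)) stop("tss positions must be >= 1 (1-based)", call. = FALSE)
    if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
    df[, need]
}

#' @rdname readGeneAnnotation
#' @export
readCpGAnnotation <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE, quote = "")
    need <- c("probe_id", "chromosome", "position", "snp_overlap")
    if (!all(need %in% colnames(df)))
        stop("CpG annotation needs columns: ", paste(need, collapse = ", "),
             call. = FALSE)
    df$position <- as.integer(df$position)
    df$snp_overlap <- as.logical(as.integer(df$snp_overlap))
    if (anyDuplicated(df$probe_id)) stop("duplicated probe_id in annotation", call. = FALSE)
    if (any(df$position < 1)) stop("positions must be >= 1 (1-based)", call. = FALSE)
    df[, need]
}

#' @rdname readGeneAnnotation
#' @param df Annotation `data.frame` to write.
#' @export
writeGeneAnnotation <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname readGeneAnnotation
#' @export
writeCpGAnnotation <- function(df, path) {
    out <- df
    out$snp_overlap <- as.integer(out$snp_overlap)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Filter probes by array detection p-value
#'
#' Retains exactly the probes whose detection p-value is below the
#' threshold in *every* sample, the standard quality filter for
#' methylation arrays. Probe order is preserved. When no detection-p
#' matrix is available the input is returned unchanged with a logged
#' notice.
#'
#' @param meth A [MethylationMatrix-class].
#' @param detectionP Optional numeric matrix of detection p-values covering
#'   every (probe, sample) cell of `meth` (row/column names matched).
#' @param threshold Detection p-value threshold in (0, 1\]; default 0.01.
#' @return A [MethylationMatrix-class] restricted to passing probes.
#' @export
filterProbes <- function(meth, detectionP = NULL, threshold = 0.01) {
    stopifnot(is(meth, "MethylationMatrix"))
    if (threshold <= 0 || threshold > 1)
        stop("threshold must lie in (0, 1]", call. = FALSE)
    if (is.null(detectionP)) {
        .mdLog("no detection p-values supplied; probe filter skipped (%d probes kept)",
               nrow(meth))
        return(meth)
    }
    if (!all(probeIds(meth) %in% rownames(detectionP)) ||
        !all(sampleIds(meth) %in% colnames(detectionP)))
        stop("detection p-value matrix does not cover all (probe, sample) cells",
             call. = FALSE)
    p <- detectionP[probeIds(meth), sampleIds(meth), drop = FALSE]
    keep <- rowSums(p < threshold) == ncol(p)
    .mdLog("detection-p filter (< %g in all %d samples): %d / %d probes retained",
           threshold, ncol(p), sum(keep), nrow(p))
    meth[keep, ]
}

#' Align expression and methylation matrices on shared samples
#'
#' Restricts both matrices to the intersection of their sample ids, in the
#' expression matrix's order (the expression order is the tie-breaking
#' authority throughout the pipeline). Dropped samples are logged. Fails
#' if fewer than 3 samples are shared, since every regression stage needs
#' at least 3 timepoints.
#'
#' @param expr An [ExpressionMatrix-class].
#' @param meth A [MethylationMatrix-class].
#' @return A list with elements `expr` and `meth`, sample-aligned.
#' @export
alignSamples <- function(expr, meth) {
    stopifnot(is(expr, "ExpressionMatrix"), is(meth, "MethylationMatrix"))
    shared <- intersect(sampleIds(expr), sampleIds(meth))
    if (length(shared) < 3)
        stop("expression and methylation share only ", length(shared),
             " samples; >= 3 required", call. = FALSE)
    shared <- sampleIds(expr)[sampleIds(expr) %in% shared]
    dropE <- setdiff(sampleIds(expr), shared)
    dropM <- setdiff(sampleIds(meth), shared)
    if (length(dropE) || length(dropM))
        .mdLog("alignSamples: dropped %d expression / %d methylation samples (%s)",
               length(dropE), length(dropM),
               paste(c(dropE, dropM), collapse = ", "))
    list(expr = expr[, shared], meth = meth[, shared])
}

#' Shapiro-Wilk normality report for a time series
#'
#' QC report on the marginal normality of a series (used descriptively,
#' never as a filter). A constant series has an undefined W statistic and
#' is reported as non-normal with a flag.
#'
#' @param series Numeric vector, 3 to 5000 values.
#' @return List with `statistic` (W), `p_value`, and `degenerate` (TRUE
#'   when the series was constant and the test undefined).
#' @export
qcNormality <- function(series) {
    n <- length(series)
    if (n < 3 || n > 5000)
        stop("qcNormality requires 3 <= length <= 5000 (got ", n, ")", call. = FALSE)
    if (length(unique(series)) == 1L)
        return(list(statistic = NA_real_, p_value = 0, degenerate = TRUE))
    sw <- stats::shapiro.test(series)
    list(statistic = unname(sw$statistic), p_value = sw$p.value, degenerate = FALSE)
}
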