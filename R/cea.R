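## Cell-type composition / expression association (CEA): per-gene nested
## linear-model ANOVA of log expression on the composition covariates.

## Internal workhorse shared by ceaTest()/ceaAnalysis(): E is genes x
## samples on the log10(FPKM+1) scale, W the samples x cell-types design.
## The composition columns sum to ~1 and are therefore near-collinear with
## the intercept; the fit goes through a rank-revealing QR so the F test
## uses numerator df = rank(M1 design) - 1, the ANOVA semantics that do
## not depend on which redundant column is dropped.
.ceaCore <- function(E, W, alpha) {
    n <- ncol(E)
    X <- cbind(`(Intercept)` = 1, W)
    qrX <- qr(X)
    r1 <- qrX$rank
    if (n <= r1)
        stop("CEA needs more timepoints (", n, ") than the design rank (",
             r1, ")", call. = FALSE)
    Q <- qr.Q(qrX)[, seq_len(r1), drop = FALSE]
    Ec <- E - rowMeans(E)
    RSS0 <- rowSums(Ec^2)
    resid <- E - (E %*% Q) %*% t(Q)
    RSS1 <- pmax(rowSums(resid^2), 0)
    q <- r1 - 1L
    dfden <- n - r1
    Fstat <- ((RSS0 - RSS1) / q) / (RSS1 / dfden)
    p <- stats::pf(Fstat, q, dfden, lower.tail = FALSE)
    # a constant gene has nothing to explain: F = 0, p = 1 by convention
    const <- RSS0 <= n * .Machine$double.eps * pmax(rowMeans(E)^2, 1)
    Fstat[const] <- 0
    p[const] <- 1
    # perfect fits: numerically zero residual variance
    perfect <- !const & RSS1 <= 1e-12 * RSS0
    Fstat[perfect] <- Inf
    p[perfect] <- 0

    ## univariate per-type regressions: slope t-test via the correlation
    sdE <- sqrt(RSS0 / (n - 1))
    sdW <- apply(W, 2L, stats::sd)
    r <- tcrossprod(Ec, t(scale(W, scale = FALSE))) /
        ((n - 1) * outer(sdE, sdW))
    r[!is.finite(r)] <- 0
    r <- pmin(pmax(r, -1), 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    ptype <- 2 * stats::pt(-abs(tstat), df = n - 2)
    ptype[abs(r) >= 1 - 1e-12] <- 0
    ptype[const, ] <- 1
    colnames(ptype) <- colnames(W)
    best <- colnames(W)[max.col(-ptype, ties.method = "first")]

    data.frame(gene_id = rownames(E), f_statistic = unname(Fstat),
               p_value = unname(p), df_num = q, df_den = dfden,
               is_cea = unname(p < alpha),
               best_cell_type = best,
               ptype, check.names = FALSE, stringsAsFactors = FALSE)
}

#' CEA test for a single gene
#'
#' Compares M1, the least-squares fit of the gene's log10(FPKM+1) series on
#' an intercept plus all cell-type proportions, against the intercept-only
#' null M0 with the ANOVA F statistic
#' `F = ((RSS0 - RSS1)/q) / (RSS1/(n - r1))`, `q = r1 - 1`, `r1` the rank
#' of the M1 design. Rank-deficient designs (the proportions sum to ~1) are
#' handled by rank-revealing QR, so duplicated or redundant composition
#' columns never change the result. Also reports the univariate regression
#' p-value for each cell type and the best (smallest-p) type, the covariate
#' the MEA composition-adjusted model uses.
#'
#' @param gene_series Numeric vector: the gene's log10(FPKM+1) values, one
#'   per sample of `comp`.
#' @param comp A [CompositionMatrix-class].
#' @param alpha Significance level for the `is_cea` call (default 0.05).
#' @return A one-row data.frame: `gene_id`, `f_statistic`, `p_value`,
#'   `df_num`, `df_den`, `is_cea`, `best_cell_type`, and one p-value
#'   column per cell type.
#' @export
ceaTest <- function(gene_series, comp, alpha = 0.05) {
    stopifnot(is(comp, "CompositionMatrix"))
    W <- proportions(comp)
    if (length(gene_series) != nrow(W))
        stop("series length does not match the composition samples", call. = FALSE)
    E <- matrix(gene_series, 1L, length(gene_series),
                dimnames = list("gene", rownames(W)))
    .ceaCore(E, W, alpha)
}

#' CEA analysis over an expression matrix
#'
#' Runs [ceaTest()] for every gene (vectorized through a shared QR of the
#' common design). Expression enters on the log10(FPKM+1) scale. No
#' multiple-testing adjustment is applied by default — genes are called
#' CEA at raw p < `cea_alpha`; `adjust = "BH"` applies
#' Benjamini-Hochberg to the F-test p-values first.
#'
#' @param expr An [ExpressionMatrix-class].
#' @param comp A [CompositionMatrix-class] over the same samples, same
#'   order.
#' @param config A [runConfig()] list (uses `cea_alpha`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data.frame with one row per gene, columns as in [ceaTest()].
#' @examples
#' d <- simulateDataset(simulationParams(n_genes = 200, n_cpgs = 700,
#'     n_dynamic_genes = 0, n_cea_genes = 20, n_mea_pairs = 0,
#'     n_signature_cpgs_per_type = 20, rng_seed = 5))
#' res <- ceaAnalysis(d$expr, d$composition)
#' sum(res$is_cea)
#' @export
ceaAnalysis <- function(expr, comp, config = runConfig(),
                        adjust = c("none", "BH")) {
    stopifnot(is(expr, "ExpressionMatrix"), is(comp, "CompositionMatrix"))
    adjust <- match.arg(adjust)
    W <- proportions(comp)
    if (!identical(sampleIds(expr), rownames(W)))
        stop("expression and composition samples differ or are out of order",
             call. = FALSE)
    E <- log10(fpkm(expr) + 1)
    res <- .ceaCore(E, W, config$cea_alpha)
    if (adjust == "BH") {
        res$p_adjusted <- stats::p.adjust(res$p_value, "BH")
        res$is_cea <- res$p_adjusted < config$cea_alpha
    }
    .mdLog("ceaAnalysis: %d of %d genes CEA at p < %g%s",
           sum(res$is_cea), nrow(res), config$cea_alpha,
           if (adjust == "BH") " (BH-adjusted)" else "")
    res
}

#' Cross-classify genes by CEA and dynamic status
#'
#' Partitions the shared gene universe into the four CEA x dynamic
#' categories and returns the 2x2 count table (the standard summary layout
#' for this analysis) plus the per-gene classification.
#'
#' @param cea_results Output of [ceaAnalysis()].
#' @param dynamic_results Output of [detectDynamicGenes()].
#' @return A list: `table` (2x2 matrix, rows dynamic/non-dynamic, columns
#'   CEA/non-CEA) and `classification` (data.frame gene_id/is_cea/
#'   is_dynamic/category).
#' @export
stratifyGenes <- function(cea_results, dynamic_results) {
    sdiff <- c(setdiff(cea_results$gene_id, dynamic_results$gene_id),
               setdiff(dynamic_results$gene_id, cea_results$gene_id))
    if (length(sdiff))
        stop("gene universes differ between CEA and dynamic results: ",
             paste(utils::head(sdiff, 10L), collapse = ", "), call. = FALSE)
    m <- match(cea_results$gene_id, dynamic_results$gene_id)
    cls <- data.frame(
        gene_id = cea_results$gene_id,
        is_cea = cea_results$is_cea,
        is_dynamic = dynamic_results$is_dynamic[m],
        stringsAsFactors = FALSE)
    cls$category <- paste0(ifelse(cls$is_dynamic, "dynamic", "non-dynamic"),
                           "/", ifelse(cls$is_cea, "CEA", "non-CEA"))
    tab <- matrix(c(sum(cls$is_dynamic & cls$is_cea),
                    sum(!cls$is_dynamic & cls$is_cea),
                    sum(cls$is_dynamic & !cls$is_cea),
                    sum(!cls$is_dynamic & !cls$is_cea)),
                  2L, 2L,
                  dimnames = list(c("dynamic", "non-dynamic"),
                                  c("CEA", "non-CEA")))
    .mdLog("stratifyGenes: dynamic/CEA %d, dynamic/non-CEA %d, non-dynamic/CEA %d, non-dynamic/non-CEA %d",
           tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    list(table = tab, classification = cls)
}
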