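## Methylation / expression association (MEA): cis gene-CpG pairing,
## reference-day-relative transformation, linear Models 1-2, Spearman
## permutation test, per-CpG SD, and the dynamic vs non-dynamic summary.

#' Extract cis gene-CpG pairs around transcription start sites
#'
#' All (gene, CpG) pairs on the same chromosome whose probe position lies
#' within `window` bases of the gene's TSS, inclusive on both ends.
#' SNP-overlapping probes are excluded first. The reported `tss_distance`
#' is strand-adjusted (positive downstream of the TSS in the gene's
#' direction of transcription); the window filter itself uses absolute
#' distance.
#'
#' @param genes Gene annotation data.frame (`gene_id`, `chromosome`,
#'   `tss`, `strand`), as from [readGeneAnnotation()].
#' @param cpgs CpG annotation data.frame (`probe_id`, `chromosome`,
#'   `position`, `snp_overlap`).
#' @param window Window half-width in bases (default 5000).
#' @return A data.frame: `gene_id`, `probe_id`, `tss_distance`.
#' @examples
#' g <- data.frame(gene_id = "g1", chromosome = "chr1", tss = 10000L,
#'                 strand = "+")
#' p <- data.frame(probe_id = c("c1", "c2"), chromosome = "chr1",
#'                 position = c(15000L, 15001L), snp_overlap = FALSE)
#' extractPairs(g, p)  # c1 included (boundary), c2 excluded
#' @export
extractPairs <- function(genes, cpgs, window = 5000L) {
    cpgs <- cpgs[!cpgs$snp_overlap, , drop = FALSE]
    nsnp <- attr(cpgs, "n_snp_removed")
    if (nrow(cpgs) == 0L || nrow(genes) == 0L) {
        .mdLog("extractPairs: empty annotation after SNP filter; no pairs")
        return(data.frame(gene_id = character(0), probe_id = character(0),
                          tss_distance = integer(0)))
    }
    gr_genes <- GenomicRanges::GRanges(
        genes$chromosome,
        IRanges::IRanges(start = pmax(genes$tss - window, 1L),
                         end = genes$tss + window))
    gr_cpgs <- GenomicRanges::GRanges(
        cpgs$chromosome, IRanges::IRanges(cpgs$position, width = 1L))
    hits <- GenomicRanges::findOverlaps(gr_genes, gr_cpgs,
                                        ignore.strand = TRUE)
    gi <- S4Vectors::queryHits(hits)
    ci <- S4Vectors::subjectHits(hits)
    d <- cpgs$position[ci] - genes$tss[gi]
    keep <- abs(d) <= window   # guard the start-clamped windows near pos 1
    gi <- gi[keep]; ci <- ci[keep]; d <- d[keep]
    out <- data.frame(gene_id = genes$gene_id[gi],
                      probe_id = cpgs$probe_id[ci],
                      tss_distance = as.integer(ifelse(genes$strand[gi] == "+",
                                                       d, -d)),
                      stringsAsFactors = FALSE)
    out <- out[order(match(out$gene_id, genes$gene_id), out$tss_distance), ]
    rownames(out) <- NULL
    if (nrow(out) == 0L) .mdLog("extractPairs: no pairs within %d bp", window)
    else .mdLog("extractPairs: %d gene-CpG pairs within %d bp of a TSS",
                nrow(out), window)
    out
}

#' Reference-day-relative transformation
#'
#' Divides a series by its value at the reference timepoint (Day 1 of the
#' time course), so the reference element is exactly 1 and the remaining
#' values are fold levels relative to it. Expression and methylation are
#' put on this common relative footing before MEA regression because FPKM
#' and beta have incommensurable definitions. A reference value smaller in
#' magnitude than `min_ref` makes the series unusable (division by ~0):
#' the result is `NULL` and callers exclude the series with a logged
#' reason rather than fabricating values.
#'
#' @param series Numeric vector.
#' @param ref_index 1-based index of the reference timepoint (default 1).
#' @param min_ref Minimum usable magnitude of the reference value
#'   (default 1e-6).
#' @return The relative series, or `NULL` if the reference value is below
#'   `min_ref` in magnitude.
#' @examples
#' relativeToReference(c(2, 4, 1))  # 1, 2, 0.5
#' @export
relativeToReference <- function(series, ref_index = 1L, min_ref = 1e-6) {
    if (ref_index < 1L || ref_index > length(series))
        stop("ref_index outside the series", call. = FALSE)
    ref <- series[ref_index]
    if (!is.finite(ref) || abs(ref) < min_ref) return(NULL)
    series / ref
}

#' MEA Model 1: expression on methylation
#'
#' Simple least squares of relative expression on an intercept plus
#' relative methylation; `r2 = 1 - RSS/TSS`, identical to the squared
#' Pearson correlation. A constant methylation series explains nothing:
#' `beta_m = 0, r2 = 0` by convention, likewise for a constant expression
#' series.
#'
#' @param e_rel Relative expression vector.
#' @param m_rel Relative methylation vector, same length >= 3.
#' @return List: `beta_m` (slope), `intercept`, `r2`.
#' @export
meaModel1 <- function(e_rel, m_rel) {
    n <- length(e_rel)
    if (length(m_rel) != n || n < 3)
        stop("need equal-length series of length >= 3", call. = FALSE)
    vm <- stats::var(m_rel)
    ve <- stats::var(e_rel)
    if (vm == 0 || ve == 0)
        return(list(beta_m = 0, intercept = mean(e_rel), r2 = 0))
    b <- stats::cov(e_rel, m_rel) / vm
    r2 <- min(stats::cor(e_rel, m_rel)^2, 1)
    list(beta_m = b, intercept = mean(e_rel) - b * mean(m_rel), r2 = r2)
}

#' MEA Model 2: expression on methylation with composition adjustment
#'
#' Joint least squares of relative expression on intercept + relative
#' methylation + the composition covariate (the proportion series of the
#' cell type with the smallest CEA univariate p for this gene). The
#' methylation-attributed R-squared is the squared Pearson correlation
#' between the composition-adjusted partial residual
#' `e_rel - b0 - b_ct * ct` and the methylation fit `b_m * m_rel` — the
#' partial-R-squared reading of how much expression variance methylation
#' explains once composition is accounted for. A constant covariate
#' reduces the model to Model 1. Collinear designs are fitted by
#' pseudo-inverse and flagged (`degenerate = TRUE`), since the split of
#' variance between the collinear predictors is then not unique.
#'
#' @param e_rel Relative expression vector.
#' @param m_rel Relative methylation vector.
#' @param ct Composition covariate vector, same length >= 4.
#' @param partial Report the partial (adjusted) R-squared (default TRUE);
#'   FALSE reports the plain joint-model R-squared.
#' @return List: `beta_m`, `beta_ct`, `intercept`, `r2_meth`,
#'   `degenerate`.
#' @export
meaModel2 <- function(e_rel, m_rel, ct, partial = TRUE) {
    n <- length(e_rel)
    if (length(m_rel) != n || length(ct) != n || n < 4)
        stop("need equal-length series of length >= 4", call. = FALSE)
    X <- cbind(1, m_rel, ct)
    qrX <- qr(X)
    degenerate <- qrX$rank < 3L
    beta <- if (degenerate) as.vector(MASS::ginv(X) %*% e_rel)
            else qr.coef(qrX, e_rel)
    beta[is.na(beta)] <- 0
    fit_m <- beta[2L] * m_rel
    adj <- e_rel - beta[1L] - beta[3L] * ct
    r2 <- if (partial) {
        if (stats::sd(fit_m) == 0 || stats::sd(adj) == 0) 0
        else min(stats::cor(adj, fit_m)^2, 1)
    } else {
        resid <- e_rel - X %*% beta
        tss <- sum((e_rel - mean(e_rel))^2)
        if (tss == 0) 0 else max(0, min(1, 1 - sum(resid^2) / tss))
    }
    list(beta_m = unname(beta[2L]), beta_ct = unname(beta[3L]),
         intercept = unname(beta[1L]), r2_meth = r2, degenerate = degenerate)
}

#' Spearman correlation with permutation p-value
#'
#' Spearman rank correlation (average ranks for ties) of expression with
#' methylation, with significance from `B` uniform random permutations of
#' the expression vector:
#' `perm_p = (1 + #permutations at least as extreme) / (B + 1)`, two-sided
#' on `|rho|` by default. The add-one numerator keeps the p-value off
#' zero (minimum attainable `1/(B+1)`). Constant input makes rho
#' undefined: reported as `rho = 0, perm_p = 1` with `degenerate = TRUE`.
#' Deterministic given the RNG state (set a seed upstream or pass `seed`).
#'
#' @param e_rel Expression vector (relative scale), length >= 3.
#' @param m_rel Methylation vector, same length.
#' @param B Number of permutations (default 1000).
#' @param two_sided Compare `|rho_b| >= |rho_obs|` (default TRUE) rather
#'   than the signed upper tail.
#' @param seed Optional integer seed applied before permuting.
#' @return List: `rho`, `perm_p`, `degenerate`.
#' @export
spearmanPermutation <- function(e_rel, m_rel, B = 1000L, two_sided = TRUE,
                                seed = NULL) {
    n <- length(e_rel)
    if (length(m_rel) != n || n < 3)
        stop("need equal-length series of length >= 3", call. = FALSE)
    if (B < 1) stop("B must be >= 1", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    re <- rank(e_rel); rm <- rank(m_rel)
    if (stats::sd(re) == 0 || stats::sd(rm) == 0)
        return(list(rho = 0, perm_p = 1, degenerate = TRUE))
    ze <- (re - mean(re)) / stats::sd(re)
    zm <- (rm - mean(rm)) / stats::sd(rm)
    rho <- sum(ze * zm) / (n - 1)
    perm <- matrix(0, n, B)
    for (b in seq_len(B)) perm[, b] <- ze[sample.int(n)]
    rho_b <- as.vector(crossprod(perm, zm)) / (n - 1)
    hits <- if (two_sided) sum(abs(rho_b) >= abs(rho) - 1e-12)
            else sum(rho_b >= rho - 1e-12)
    list(rho = rho, perm_p = (1 + hits) / (B + 1), degenerate = FALSE)
}

#' Per-CpG methylation standard deviation
#'
#' Sample SD (n-1 denominator) of the raw beta series — the temporal
#' stability measure for a CpG, computed on the original \[0,1\] scale,
#' not on Day-1-relative values.
#'
#' @param beta_series Numeric vector of beta values, length >= 2.
#' @return The sample SD.
#' @export
methylationSD <- function(beta_series) {
    if (length(beta_series) < 2) stop("need length >= 2", call. = FALSE)
    stats::sd(beta_series)
}

#' Compare two value distributions (dynamic vs non-dynamic pairs)
#'
#' Two-sided Mann-Whitney U test (normal approximation with continuity and
#' tie correction) by default, or two-sample Kolmogorov-Smirnov. Reports
#' medians and IQRs for both groups alongside the test. With a group of
#' fewer than 2 values only the summaries are returned and the p-value is
#' omitted with a flag.
#'
#' @param x,y Numeric vectors (e.g. R-squared values of pairs at dynamic
#'   and non-dynamic genes).
#' @param test `"mwu"` (default) or `"ks"`.
#' @return List: `statistic`, `p_value` (NA when flagged), `summary`
#'   (data.frame of group n/median/q1/q3), `insufficient`.
#' @export
compareDistributions <- function(x, y, test = c("mwu", "ks")) {
    test <- match.arg(test)
    if (!length(x) || !length(y))
        stop("both groups must be nonempty", call. = FALSE)
    qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    sx <- qs(x); sy <- qs(y)
    summ <- data.frame(group = c("x", "y"), n = c(length(x), length(y)),
                       median = c(sx[2], sy[2]), q1 = c(sx[1], sy[1]),
                       q3 = c(sx[3], sy[3]))
    if (length(x) < 2 || length(y) < 2)
        return(list(statistic = NA_real_, p_value = NA_real_, summary = summ,
                    insufficient = TRUE))
    ht <- if (test == "mwu")
        suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    else suppressWarnings(stats::ks.test(x, y))
    list(statistic = unname(ht$statistic), p_value = min(ht$p.value, 1),
         summary = summ, insufficient = FALSE)
}

#' Run the full MEA stage
#'
#' For every cis gene-CpG pair: transform the gene's log10(FPKM+1) series
#' and the probe's beta series to Day-1-relative values, fit Model 1 (and
#' Model 2 when a composition is supplied, using the gene's best CEA cell
#' type as covariate), run the Spearman permutation test, and record the
#' probe's raw-beta SD. By default genes called CEA are removed first, so
#' composition-driven expression cannot masquerade as a methylation
#' effect; `config$stratify_cea = FALSE` keeps them (relying on Model-2
#' adjustment instead). Pairs whose reference-day value is below
#' `config$min_ref` on either side are excluded with a logged count.
#'
#' The summary reports, separately for pairs at dynamic and non-dynamic
#' genes: median and IQR of the Model-1 R-squared, the permutation
#' p-values and the methylation SDs; the fraction of pairs with
#' perm_p < 0.05; and the distribution-comparison p-values between the two
#' groups.
#'
#' @param expr An [ExpressionMatrix-class].
#' @param meth A sample-aligned [MethylationMatrix-class].
#' @param pairs Pair table from [extractPairs()].
#' @param cea_results Output of [ceaAnalysis()].
#' @param dynamic_results Output of [detectDynamicGenes()].
#' @param composition Optional [CompositionMatrix-class] for Model 2.
#' @param config A [runConfig()] list.
#' @return List: `results` (one row per analysed pair: ids, tss_distance,
#'   `r2_model1`, `beta_m`, `r2_model2` (NA without composition),
#'   `spearman_rho`, `perm_p`, `meth_sd`, `is_dynamic`, `is_cea`,
#'   `gene_class`) and `summary` (list described above).
#' @export
runMEA <- function(expr, meth, pairs, cea_results, dynamic_results,
                   composition = NULL, config = runConfig()) {
    stopifnot(is(expr, "ExpressionMatrix"), is(meth, "MethylationMatrix"))
    .assertAligned(expr, meth)
    set.seed(.childSeed(config$rng_seed, 9L))
    logE <- log10(fpkm(expr) + 1)
    B <- betaValues(meth)
    W <- if (!is.null(composition)) proportions(composition) else NULL
    if (!is.null(W) && !identical(rownames(W), sampleIds(expr)))
        stop("composition samples differ from the expression samples", call. = FALSE)

    keep <- pairs$gene_id %in% rownames(logE) & pairs$probe_id %in% rownames(B)
    pairs <- pairs[keep, , drop = FALSE]
    cea_idx <- match(pairs$gene_id, cea_results$gene_id)
    dyn_idx <- match(pairs$gene_id, dynamic_results$gene_id)
    if (anyNA(cea_idx) || anyNA(dyn_idx))
        stop("pairs reference genes missing from the CEA or dynamic results",
             call. = FALSE)
    is_cea <- cea_results$is_cea[cea_idx]
    if (config$stratify_cea) {
        .mdLog("runMEA: excluding %d pair(s) at CEA genes (stratified analysis)",
               sum(is_cea))
        keep <- !is_cea
        pairs <- pairs[keep, , drop = FALSE]
        cea_idx <- cea_idx[keep]; dyn_idx <- dyn_idx[keep]
        is_cea <- is_cea[keep]
    }
    is_dyn <- dynamic_results$is_dynamic[dyn_idx]
    best_ct <- cea_results$best_cell_type[cea_idx]

    ref <- config$reference_day_index
    n <- nrow(pairs)
    res <- data.frame(pairs, r2_model1 = NA_real_, beta_m = NA_real_,
                      r2_model2 = NA_real_, spearman_rho = NA_real_,
                      perm_p = NA_real_, meth_sd = NA_real_,
                      is_dynamic = is_dyn, is_cea = is_cea,
                      stringsAsFactors = FALSE)
    excluded <- 0L
    for (i in seq_len(n)) {
        e_rel <- relativeToReference(logE[pairs$gene_id[i], ], ref, config$min_ref)
        m_rel <- relativeToReference(B[pairs$probe_id[i], ], ref, config$min_ref)
        if (is.null(e_rel) || is.null(m_rel)) {
            excluded <- excluded + 1L
            next
        }
        m1 <- meaModel1(e_rel, m_rel)
        res$r2_model1[i] <- m1$r2
        res$beta_m[i] <- m1$beta_m
        if (!is.null(W))
            res$r2_model2[i] <- meaModel2(e_rel, m_rel, W[, best_ct[i]],
                                          partial = config$model2_partial)$r2_meth
        sp <- spearmanPermutation(e_rel, m_rel, B = config$n_permutations,
                                  two_sided = config$perm_two_sided)
        res$spearman_rho[i] <- sp$rho
        res$perm_p[i] <- sp$perm_p
        res$meth_sd[i] <- methylationSD(B[pairs$probe_id[i], ])
    }
    if (excluded)
        .mdLog("runMEA: %d pair(s) excluded (reference-day value below %g)",
               excluded, config$min_ref)
    ok <- !is.na(res$r2_model1)
    res <- res[ok, , drop = FALSE]
    rownames(res) <- NULL
    res$gene_class <- paste0(ifelse(res$is_dynamic, "dynamic", "non-dynamic"),
                             "/", ifelse(res$is_cea, "CEA", "non-CEA"))

    grp <- function(col) split(res[[col]], ifelse(res$is_dynamic, "dynamic",
                                                  "non_dynamic"))
    summarize <- function(v) {
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
        c(n = length(v), median = q[2], q1 = q[1], q3 = q[3])
    }
    both <- sum(res$is_dynamic) > 0 && sum(!res$is_dynamic) > 0
    cmp <- function(col) {
        g <- grp(col)
        if (both) compareDistributions(g$dynamic, g$non_dynamic,
                                       test = config$dist_test)
        else list(statistic = NA_real_, p_value = NA_real_,
                  summary = NULL, insufficient = TRUE)
    }
    summary <- list(
        n_pairs = nrow(res),
        r2 = lapply(grp("r2_model1"), summarize),
        perm_p = lapply(grp("perm_p"), summarize),
        meth_sd = lapply(grp("meth_sd"), summarize),
        frac_perm_p_lt_05 = mean(res$perm_p < 0.05),
        frac_perm_p_lt_05_by_group = vapply(grp("perm_p"),
                                            function(v) mean(v < 0.05), 0),
        compare_r2 = cmp("r2_model1"),
        compare_meth_sd = cmp("meth_sd"))
    .mdLog("runMEA: %d pairs analysed; median Model-1 R2 = %.3f; %.1f%% of pairs at perm p < 0.05",
           nrow(res), stats::median(res$r2_model1),
           100 * summary$frac_perm_p_lt_05)
    list(results = res, summary = summary)
}
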