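## Dynamic-gene detection: genes whose expression coefficient of variation
## is a Smirnov-Grubbs outlier within its bin of mean log10(FPKM+1).

#' Bin genes by mean log expression
#'
#' Bin index is `floor(mean_log_expr / bin_width)`; bins are left-closed,
#' right-open, so a value exactly on a left edge belongs to that bin.
#'
#' @param mean_log_expr Numeric vector of per-gene mean log10(FPKM+1).
#' @param bin_width Bin width on the log10 scale (default 0.05).
#' @return Integer vector of bin indices.
#' @examples
#' binByMeanLogExpression(c(0.07, 0.05, 0.049))  # 1, 1, 0
#' @export
binByMeanLogExpression <- function(mean_log_expr, bin_width = 0.05) {
    if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
    as.integer(floor(mean_log_expr / bin_width))
}

#' Coefficient of variation of an expression series
#'
#' Sample SD (n-1 denominator) divided by the mean, computed on
#' log10(FPKM+1) when `scale = "log"` (the same axis the bins use) or on
#' raw FPKM when `scale = "raw"`. A series whose mean is zero on the
#' analysis scale has no defined CV and returns `NA` (the caller excludes
#' and logs such genes).
#'
#' @param series Numeric vector of FPKM values, length >= 2.
#' @param scale `"log"` (default) or `"raw"`.
#' @return The CV, or `NA` if the mean on the analysis scale is 0.
#' @examples
#' computeCV(c(1, 2, 3), scale = "raw")  # sd 1 / mean 2 = 0.5
#' @export
computeCV <- function(series, scale = c("log", "raw")) {
    scale <- match.arg(scale)
    if (length(series) < 2) stop("series must have length >= 2", call. = FALSE)
    x <- if (scale == "log") log10(series + 1) else series
    m <- mean(x)
    if (m <= 0) return(NA_real_)
    stats::sd(x) / m
}

#' Grubbs critical value
#'
#' Critical value of the (one-sided upper) Grubbs statistic
#' `G = (max(x) - mean(x)) / sd(x)` at level `alpha` for `n` values:
#' `G_crit = ((n-1)/sqrt(n)) sqrt(t^2 / (n-2+t^2))` with `t` the upper
#' `alpha/n` quantile of Student's t with `n-2` degrees of freedom
#' (`alpha/(2n)` for the two-sided test).
#'
#' @param n Sample size, >= 3.
#' @param alpha Significance level in (0, 1).
#' @param one_sided Upper-tail test (default TRUE).
#' @return The critical value.
#' @export
grubbsCritical <- function(n, alpha = 0.05, one_sided = TRUE) {
    if (any(n < 3)) stop("Grubbs test needs n >= 3", call. = FALSE)
    p <- if (one_sided) alpha / n else alpha / (2 * n)
    t <- stats::qt(p, df = n - 2, lower.tail = FALSE)
    ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterative Smirnov-Grubbs outlier detection
#'
#' At each pass the studentized deviation of the current maximum,
#' `G = (max(x) - mean(x)) / sd(x)`, is compared with [grubbsCritical()];
#' if it exceeds the critical value the maximum is flagged and removed and
#' the test repeats, until no rejection or fewer than `min_size` values
#' remain. Ties at the maximum flag the first index (callers order values
#' lexicographically by gene id for determinism). A constant vector yields
#' no outliers.
#'
#' @param values Numeric vector, length >= `min_size`.
#' @param alpha Significance level per pass (default 0.05).
#' @param one_sided Flag only high outliers (default TRUE). The two-sided
#'   variant tests the value farthest from the mean in either direction.
#' @param min_size Minimum remaining sample size (default 3).
#' @param iterate Repeat until no rejection (default TRUE); FALSE runs one
#'   pass.
#' @return A data.frame with one row per flagged value: `index` (into
#'   `values`, in flagging order), `statistic` (G at its pass),
#'   `critical`, and `pass`.
#' @examples
#' grubbsOutliers(c(1, 1, 1, 1, 10))
#' @export
grubbsOutliers <- function(values, alpha = 0.05, one_sided = TRUE,
                           min_size = 3L, iterate = TRUE) {
    if (length(values) < min_size)
        stop("need at least ", min_size, " values", call. = FALSE)
    idx <- seq_along(values)
    out <- list()
    pass <- 0L
    repeat {
        pass <- pass + 1L
        n <- length(idx)
        if (n < min_size) break
        x <- values[idx]
        s <- stats::sd(x)
        if (!is.finite(s) || s == 0) break
        if (one_sided) {
            i <- which.max(x)
            G <- (x[i] - mean(x)) / s
        } else {
            dev <- abs(x - mean(x))
            i <- which.max(dev)
            G <- dev[i] / s
        }
        Gc <- grubbsCritical(n, alpha, one_sided)
        if (G <= Gc) break
        out[[pass]] <- data.frame(index = idx[i], statistic = G,
                                  critical = Gc, pass = pass)
        idx <- idx[-i]
        if (!iterate) break
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(index = integer(0), statistic = numeric(0),
                    critical = numeric(0), pass = integer(0))
}

#' Detect dynamically expressed genes
#'
#' The per-gene mean of log10(FPKM+1) over timepoints assigns each gene to
#' a 0.05-wide expression bin; within each bin holding at least
#' `min_bin_size` genes, CV outliers are flagged by the iterative
#' Smirnov-Grubbs test and defined as dynamically expressed. Genes with
#' zero mean on the analysis scale (undefined CV) are excluded before
#' binning and logged.
#'
#' @param expr An [ExpressionMatrix-class].
#' @param config A [runConfig()] list (uses `bin_width`, `grubbs_alpha`,
#'   `cv_scale`, `min_bin_size`, `grubbs_iterate`, `grubbs_one_sided`,
#'   `min_mean_fpkm`).
#' @return A data.frame with one row per analysed gene: `gene_id`,
#'   `mean_log_expr`, `bin_index`, `cv`, `grubbs_statistic` (the G value
#'   at the pass a flagged gene was removed; the first-pass studentized
#'   deviation otherwise), `is_dynamic`, and `pass_index` (0 = never
#'   flagged).
#' @examples
#' d <- simulateDataset(simulationParams(n_genes = 300, n_cpgs = 700,
#'     n_dynamic_genes = 5, n_cea_genes = 0, n_mea_pairs = 0,
#'     n_signature_cpgs_per_type = 20, rng_seed = 2))
#' res <- detectDynamicGenes(d$expr)
#' table(res$is_dynamic)
#' @export
detectDynamicGenes <- function(expr, config = runConfig()) {
    stopifnot(is(expr, "ExpressionMatrix"))
    F <- fpkm(expr)
    if (config$min_mean_fpkm > 0) {
        keep <- rowMeans(F) >= config$min_mean_fpkm
        .mdLog("expression filter (mean FPKM >= %g): %d / %d genes kept",
               config$min_mean_fpkm, sum(keep), nrow(F))
        F <- F[keep, , drop = FALSE]
    }
    logF <- log10(F + 1)
    mlog <- rowMeans(logF)
    cv <- vapply(seq_len(nrow(F)), function(i)
        computeCV(F[i, ], scale = config$cv_scale), numeric(1))
    usable <- !is.na(cv) & mlog > 0
    if (any(!usable))
        .mdLog("detectDynamicGenes: %d gene(s) with zero mean excluded from testing",
               sum(!usable))
    res <- data.frame(
        gene_id = rownames(F), mean_log_expr = unname(mlog),
        bin_index = binByMeanLogExpression(mlog, config$bin_width),
        cv = unname(cv), grubbs_statistic = NA_real_,
        is_dynamic = FALSE, pass_index = 0L, stringsAsFactors = FALSE)
    skipped <- 0L
    for (b in unique(res$bin_index[usable])) {
        rows <- which(usable & res$bin_index == b)
        rows <- rows[order(res$gene_id[rows])]   # lexicographic tie-break
        if (length(rows) < config$min_bin_size) {
            skipped <- skipped + 1L
            next
        }
        x <- res$cv[rows]
        if (stats::sd(x) > 0)
            res$grubbs_statistic[rows] <- (x - mean(x)) / stats::sd(x)
        fl <- grubbsOutliers(x, alpha = config$grubbs_alpha,
                             one_sided = config$grubbs_one_sided,
                             min_size = config$min_bin_size,
                             iterate = config$grubbs_iterate)
        if (nrow(fl)) {
            res$is_dynamic[rows[fl$index]] <- TRUE
            res$pass_index[rows[fl$index]] <- fl$pass
            res$grubbs_statistic[rows[fl$index]] <- fl$statistic
        }
    }
    if (skipped)
        .mdLog("detectDynamicGenes: %d bin(s) below min_bin_size skipped", skipped)
    nd <- sum(res$is_dynamic)
    .mdLog("detectDynamicGenes: %d of %d genes dynamic (%.1f%%)",
           nd, sum(usable), 100 * nd / max(sum(usable), 1L))
    res
}
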