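#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' Defaults follow the published analysis where it states a value (0.05-wide
#' expression bins, 5,000-bp TSS window, 1,000 permutations, raw p < 0.05
#' significance) and documented package choices elsewhere.
#'
#' @param bin_width Width of the mean-log10(FPKM+1) bins used for
#'   dynamic-gene detection. Default 0.05.
#' @param grubbs_alpha Significance level of the Smirnov-Grubbs outlier
#'   test within each bin. Default 0.05.
#' @param cea_alpha Significance level for calling a gene cell-type
#'   composition associated. Default 0.05.
#' @param tss_window_bp Maximum absolute distance (bases) between a CpG
#'   probe and a gene TSS for cis pairing; inclusive on both ends.
#'   Default 5000.
#' @param n_permutations Number of random permutations of the expression
#'   vector in the Spearman permutation test. Default 1000.
#' @param reference_day_index 1-based index of the reference timepoint used
#'   for the relative transformation (Day 1 of the time course). Default 1.
#' @param rng_seed Integer seed for all stochastic stages. Default 1.
#' @param cv_scale Scale on which the coefficient of variation is computed:
#'   `"log"` (log10(FPKM+1), the binning axis; default) or `"raw"` (FPKM).
#' @param min_bin_size Minimum number of genes a bin must hold for the
#'   Grubbs test to run (and the floor below which iterative removal
#'   stops). Default 3.
#' @param grubbs_iterate Repeat single-outlier Grubbs removal until no
#'   rejection (default TRUE); FALSE runs a single pass.
#' @param grubbs_one_sided Flag only unusually *high* CVs (default TRUE).
#' @param min_ref Minimum magnitude of the reference-day value for a series
#'   to be usable in the relative transform. Default 1e-6.
#' @param stratify_cea Remove CEA genes before the MEA per-pair analysis
#'   (default TRUE); FALSE keeps all genes and relies on Model-2
#'   composition adjustment.
#' @param normalize_composition Rescale each deconvolved proportion vector
#'   to sum to one (default FALSE, keeping the raw projection).
#' @param perm_two_sided Permutation p on the absolute Spearman rho
#'   (default TRUE) or one-sided.
#' @param model2_partial Compute the Model-2 methylation R-squared as the
#'   partial (composition-adjusted) correlation form (default TRUE); FALSE
#'   reports the plain joint-model R-squared.
#' @param dist_test Two-sample test for dynamic vs non-dynamic
#'   distribution comparisons: `"mwu"` (Mann-Whitney U, default) or
#'   `"ks"` (Kolmogorov-Smirnov).
#' @param min_mean_fpkm Optional expression filter: genes whose mean FPKM
#'   is below this are dropped before analysis. Default 0 (off).
#' @return A named list of class `"RunConfig"`.
#' @examples
#' cfg <- runConfig(n_permutations = 200)
#' cfg$tss_window_bp
#' @export
runConfig <- function(bin_width = 0.05,
                      grubbs_alpha = 0.05,
                      cea_alpha = 0.05,
                      tss_window_bp = 5000,
                      n_permutations = 1000,
                      reference_day_index = 1L,
                      rng_seed = 1L,
                      cv_scale = c("log", "raw"),
                      min_bin_size = 3L,
                      grubbs_iterate = TRUE,
                      grubbs_one_sided = TRUE,
                      min_ref = 1e-6,
                      stratify_cea = TRUE,
                      normalize_composition = FALSE,
                      perm_two_sided = TRUE,
                      model2_partial = TRUE,
                      dist_test = c("mwu", "ks"),
                      min_mean_fpkm = 0) {
    cv_scale <- match.arg(cv_scale)
    dist_test <- match.arg(dist_test)
    if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
    for (a in c(grubbs_alpha, cea_alpha))
        if (a <= 0 || a >= 1) stop("alpha levels must lie in (0, 1)", call. = FALSE)
    if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
    if (tss_window_bp < 0) stop("tss_window_bp must be >= 0", call. = FALSE)
    if (min_bin_size < 3) stop("min_bin_size must be >= 3", call. = FALSE)
    if (reference_day_index < 1) stop("reference_day_index must be >= 1", call. = FALSE)
    structure(list(
        bin_width = bin_width, grubbs_alpha = grubbs_alpha,
        cea_alpha = cea_alpha, tss_window_bp = as.integer(tss_window_bp),
        n_permutations = as.integer(n_permutations),
        reference_day_index = as.integer(reference_day_index),
        rng_seed = as.integer(rng_seed), cv_scale = cv_scale,
        min_bin_size = as.integer(min_bin_size),
        grubbs_iterate = isTRUE(grubbs_iterate),
        grubbs_one_sided = isTRUE(grubbs_one_sided),
        min_ref = min_ref, stratify_cea = isTRUE(stratify_cea),
        normalize_composition = isTRUE(normalize_composition),
        perm_two_sided = isTRUE(perm_two_sided),
        model2_partial = isTRUE(model2_partial),
        dist_test = dist_test, min_mean_fpkm = min_mean_fpkm),
        class = "RunConfig")
}

#' Read a run configuration from a flat key = value text file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Keys mirror the arguments of [runConfig()]; unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return A `"RunConfig"` list, as from [runConfig()].
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "\\s*[=:]\\s*")
    keys <- vapply(kv, `[`, "", 1L)
    vals <- vapply(kv, `[`, "", 2L)
    known <- names(formals(runConfig))
    bad <- setdiff(keys, known)
    if (length(bad))
        stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
    args <- lapply(seq_along(keys), function(i) {
        v <- vals[i]
        if (keys[i] %in% c("cv_scale", "dist_test")) return(v)
        if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
        as.numeric(v)
    })
    names(args) <- keys
    do.call(runConfig, args)
}
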