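#' Run the complete analysis pipeline
#'
#' Orchestrates every stage on a dataset (as returned by
#' [simulateDataset()] or assembled from the TSV readers): detection-p
#' probe filter, sample alignment, reference-based deconvolution,
#' dynamic-gene detection, CEA classification and stratification, cis pair
#' extraction, and the MEA stage.
#'
#' @param dataset A list with `expr`, `meth`, `signature`,
#'   `gene_annotation`, `cpg_annotation`, and optionally `detection_p`.
#' @param config A [runConfig()] list.
#' @return A list: `composition` (estimated), `composition_qc`, `dynamic`,
#'   `cea`, `stratification`, `pairs`, `mea`, and `config`.
#' @examples
#' d <- simulateDataset(simulationParams(n_genes = 150, n_cpgs = 500,
#'     n_dynamic_genes = 4, n_cea_genes = 4, n_mea_pairs = 4,
#'     n_signature_cpgs_per_type = 20, rng_seed = 11))
#' out <- runPipeline(d, runConfig(n_permutations = 100))
#' out$stratification$table
#' @export
runPipeline <- function(dataset, config = runConfig()) {
    meth <- filterProbes(dataset$meth, dataset$detection_p)
    al <- alignSamples(dataset$expr, meth)
    expr <- al$expr; meth <- al$meth

    composition <- estimateComposition(meth, dataset$signature,
                                       normalize = config$normalize_composition)
    qc <- compositionQC(composition)
    dynamic <- detectDynamicGenes(expr, config)
    cea <- ceaAnalysis(expr, composition, config)
    strat <- stratifyGenes(cea, dynamic)
    pairs <- extractPairs(dataset$gene_annotation, dataset$cpg_annotation,
                          window = config$tss_window_bp)
    mea <- runMEA(expr, meth, pairs, cea, dynamic,
                  composition = composition, config = config)
    list(composition = composition, composition_qc = qc, dynamic = dynamic,
         cea = cea, stratification = strat, pairs = pairs, mea = mea,
         config = config)
}
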