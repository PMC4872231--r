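# Shared fixture builders: everything is generated in code at test time.

smallParams <- function(seed = 1L, ...) {
    defaults <- list(n_genes = 200L, n_cpgs = 800L, n_dynamic_genes = 8L,
                     n_cea_genes = 8L, n_mea_pairs = 8L,
                     n_signature_cpgs_per_type = 25L, rng_seed = seed)
    do.call(simulationParams, utils::modifyList(defaults, list(...)))
}

randomExprMatrix <- function(nGenes = 10, nSamples = 5, seed = 1) {
    set.seed(seed)
    m <- matrix(round(rexp(nGenes * nSamples, rate = 0.1), 4),
                nGenes, nSamples,
                dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                sprintf("Day%d", seq_len(nSamples))))
    ExpressionMatrix(m)
}

randomMethMatrix <- function(nProbes = 10, nSamples = 5, seed = 1) {
    set.seed(seed)
    m <- matrix(round(runif(nProbes * nSamples), 6), nProbes, nSamples,
                dimnames = list(sprintf("c%03d", seq_len(nProbes)),
                                sprintf("Day%d", seq_len(nSamples))))
    MethylationMatrix(m)
}

simplexVector <- function(k, seed = 1) {
    set.seed(seed)
    x <- runif(k)
    x / sum(x)
}
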