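## Synthetic longitudinal mixed-cell dataset with planted structure.
##
## The generator emulates a 24-timepoint within-individual blood design:
## ~6 leukocyte cell types with Dirichlet day-to-day composition noise, a
## bimodal 450K-like beta-value marginal with per-CpG temporal SD ~ 0.01,
## stimulus-responsive "dynamic" genes spiking at chosen days, genes driven
## by one cell type's proportion (CEA positives), and gene-CpG pairs whose
## expression is linearly coupled to a slowly drifting methylation series
## at a chosen population R-squared (MEA positives). Ground truth for every
## planted feature is recorded so each inference stage can be scored.

#' Simulation parameters
#'
#' All knobs of the synthetic-data generator, validated in one place.
#' Defaults describe the emulated study: 24 timepoints, 6 leukocyte cell
#' types (CD8T, CD4T, NK, B cell, monocyte, granulocyte — labels only, no
#' biology is computed from the names), per-CpG temporal SD 0.01, and a
#' mid-series stimulus day for the dynamic genes.
#'
#' @param n_timepoints Number of timepoints (days). Default 24.
#' @param n_genes Number of genes. Default 5000.
#' @param n_cpgs Total number of CpG probes (baseline + planted MEA +
#'   signature). Default 20000.
#' @param cell_types Character labels of the cell types; their length sets
#'   the number of types.
#' @param dirichlet_base Mean proportion per cell type; must sum to 1.
#'   Default is a typical whole-blood leukocyte panel.
#' @param dirichlet_concentration Dirichlet concentration controlling
#'   day-to-day composition variability; larger is more stable. Default
#'   150 (per-type SD of a few percentage points).
#' @param n_dynamic_genes Planted stimulus-responsive genes. Default 50.
#' @param dynamic_fold Multiplicative FPKM spike applied at `spike_days`.
#'   Default 4.
#' @param spike_days Timepoint indices carrying the stimulus response.
#'   Default 12 (one mid-series episode).
#' @param n_cea_genes Planted composition-driven genes. Default 100.
#' @param cea_effect Expression scale of the driving cell type for CEA
#'   genes (the gene is expressed in that type only). Default 3.
#' @param n_mea_pairs Planted methylation-coupled gene-CpG pairs.
#'   Default 50.
#' @param mea_target_r2 Population proportion of expression variance driven
#'   by methylation in planted pairs, in \[0, 1\]. Default 0.5.
#' @param meth_temporal_sd Temporal SD of baseline CpG beta values.
#'   Default 0.01.
#' @param expr_noise_sd SD of the multiplicative log-normal expression
#'   noise. Default 0.05.
#' @param n_signature_cpgs_per_type Signature CpGs per cell type emitted
#'   for deconvolution. Default 100.
#' @param snp_fraction Fraction of baseline probes flagged as
#'   SNP-overlapping in the annotation. Default 0.02.
#' @param rng_seed Master seed; every stage derives its own child seed from
#'   it deterministically. Default 1.
#' @return A validated list of class `"SimulationParams"`.
#' @examples
#' p <- simulationParams(n_genes = 200, n_cpgs = 800, n_dynamic_genes = 5,
#'                       n_cea_genes = 5, n_mea_pairs = 5,
#'                       n_signature_cpgs_per_type = 20)
#' @export
simulationParams <- function(n_timepoints = 24L,
                             n_genes = 5000L,
                             n_cpgs = 20000L,
                             cell_types = c("CD8T", "CD4T", "NK", "Bcell",
                                            "Mono", "Gran"),
                             dirichlet_base = c(0.10, 0.15, 0.05, 0.05,
                                                0.10, 0.55),
                             dirichlet_concentration = 150,
                             n_dynamic_genes = 50L,
                             dynamic_fold = 4,
                             spike_days = 12L,
                             n_cea_genes = 100L,
                             cea_effect = 3,
                             n_mea_pairs = 50L,
                             mea_target_r2 = 0.5,
                             meth_temporal_sd = 0.01,
                             expr_noise_sd = 0.05,
                             n_signature_cpgs_per_type = 100L,
                             snp_fraction = 0.02,
                             rng_seed = 1L) {
    k <- length(cell_types)
    if (k < 2) stop("need >= 2 cell types", call. = FALSE)
    if (length(dirichlet_base) != k)
        stop("dirichlet_base must have one entry per cell type", call. = FALSE)
    if (abs(sum(dirichlet_base) - 1) > 1e-8)
        stop("dirichlet_base must sum to 1", call. = FALSE)
    if (dirichlet_concentration <= 0)
        stop("dirichlet_concentration must be > 0", call. = FALSE)
    counts <- c(n_timepoints, n_genes, n_cpgs, n_dynamic_genes, n_cea_genes,
                n_mea_pairs, n_signature_cpgs_per_type)
    if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
    if (n_dynamic_genes + n_cea_genes + n_mea_pairs > n_genes)
        stop("planted gene categories exceed n_genes", call. = FALSE)
    if (n_mea_pairs + k * n_signature_cpgs_per_type > n_cpgs)
        stop("planted + signature CpGs exceed n_cpgs", call. = FALSE)
    if (mea_target_r2 < 0 || mea_target_r2 > 1)
        stop("mea_target_r2 must lie in [0, 1]", call. = FALSE)
    if (any(spike_days < 1) || any(spike_days > n_timepoints))
        stop("spike_days outside the time course", call. = FALSE)
    structure(list(
        n_timepoints = as.integer(n_timepoints), n_genes = as.integer(n_genes),
        n_cpgs = as.integer(n_cpgs), cell_types = cell_types,
        dirichlet_base = dirichlet_base,
        dirichlet_concentration = dirichlet_concentration,
        n_dynamic_genes = as.integer(n_dynamic_genes),
        dynamic_fold = dynamic_fold, spike_days = as.integer(spike_days),
        n_cea_genes = as.integer(n_cea_genes), cea_effect = cea_effect,
        n_mea_pairs = as.integer(n_mea_pairs), mea_target_r2 = mea_target_r2,
        meth_temporal_sd = meth_temporal_sd, expr_noise_sd = expr_noise_sd,
        n_signature_cpgs_per_type = as.integer(n_signature_cpgs_per_type),
        snp_fraction = snp_fraction, rng_seed = as.integer(rng_seed)),
        class = "SimulationParams")
}

.dayLabels <- function(n) sprintf("Day%d", seq_len(n))

#' Simulate per-timepoint cell-type composition
#'
#' One Dirichlet draw per timepoint around `dirichlet_base` with
#' concentration `dirichlet_concentration` (implemented as normalized
#' gamma draws). Rows sum to one exactly.
#'
#' @param params A [simulationParams()] list.
#' @param seed Integer seed; defaults to a child of `params$rng_seed`.
#' @return A [CompositionMatrix-class], timepoints x cell types.
#' @export
simulateComposition <- function(params, seed = .childSeed(params$rng_seed, 1L)) {
    set.seed(seed)
    k <- length(params$cell_types)
    shape <- params$dirichlet_base * params$dirichlet_concentration
    g <- matrix(stats::rgamma(params$n_timepoints * k,
                              shape = rep(shape, each = params$n_timepoints)),
                nrow = params$n_timepoints, ncol = k)
    w <- g / rowSums(g)
    dimnames(w) <- list(.dayLabels(params$n_timepoints), params$cell_types)
    CompositionMatrix(w)
}

#' Simulate planted methylation-coupled gene-CpG pairs
#'
#' For each planted pair, the CpG beta series is a slow sinusoidal drift
#' (baseline U(0.35, 0.65), amplitude U(0.05, 0.15), small jitter), and the
#' gene's log10(FPKM+1) series is `a + b (M - mean(M)) + noise` with slope
#' sign random, the slope magnitude set so `|b| sd(M) = 0.1`, and the noise
#' variance chosen so that, conditional on the realized methylation series,
#' the population R-squared of the regression of expression on methylation
#' equals `mea_target_r2` exactly. `mea_target_r2 = 1` yields a noiseless
#' pair; `0` yields independence.
#'
#' @param params A [simulationParams()] list.
#' @param seed Integer seed.
#' @return List with `expr_log` (pairs x timepoints matrix of
#'   log10(FPKM+1)), `meth` (pairs x timepoints beta matrix), and `pairs`
#'   (data.frame of slope/intercept/target R-squared per pair).
#' @export
simulateMethylationCoupled <- function(params,
                                       seed = .childSeed(params$rng_seed, 2L)) {
    set.seed(seed)
    n <- params$n_mea_pairs
    T <- params$n_timepoints
    r2 <- params$mea_target_r2
    M <- matrix(0, n, T)
    E <- matrix(0, n, T)
    info <- data.frame(intercept = numeric(n), slope = numeric(n),
                       target_r2 = rep(r2, n))
    tgrid <- seq_len(T)
    for (i in seq_len(n)) {
        m0 <- stats::runif(1, 0.35, 0.65)
        amp <- stats::runif(1, 0.05, 0.15)
        ph <- stats::runif(1, 0, 2 * pi)
        m <- m0 + amp * sin(2 * pi * tgrid / T + ph) +
            stats::rnorm(T, 0, 0.003)
        m <- pmin(pmax(m, 0.01), 0.99)
        a <- stats::runif(1, 0.8, 2.0)
        sdm <- stats::sd(m)
        if (r2 == 0) {
            b <- 0
            sdxi <- 0.1
        } else {
            b <- sample(c(-1, 1), 1) * 0.1 / sdm
            sdxi <- if (r2 == 1) 0 else abs(b) * sdm * sqrt((1 - r2) / r2)
        }
        e <- a + b * (m - mean(m)) + stats::rnorm(T, 0, sdxi)
        e <- pmax(e, 0)   # log10(FPKM+1) cannot be negative
        M[i, ] <- m
        E[i, ] <- e
        info$intercept[i] <- a
        info$slope[i] <- b
    }
    list(expr_log = E, meth = M, pairs = info)
}

#' Simulate the gene-expression matrix
#'
#' Baseline genes mix cell-type-specific expression levels through the
#' composition: `FPKM_gt = sum_k w_tk e_gk exp(eps_gt)` with `e_gk`
#' log-normal around a per-gene base level (spread so mean log10(FPKM+1)
#' covers roughly 0.3-2.5, populating many detection bins) and
#' `eps ~ N(0, expr_noise_sd^2)`. Planted dynamic genes are multiplied by
#' `dynamic_fold` at `spike_days`; planted CEA genes are expressed in a
#' single cell type (level `cea_effect` times the base), so their series
#' tracks that type's proportion; planted MEA genes take the coupled rows
#' from [simulateMethylationCoupled()].
#'
#' @param params A [simulationParams()] list.
#' @param composition A [CompositionMatrix-class] with
#'   `params$n_timepoints` rows.
#' @param coupled Output of [simulateMethylationCoupled()].
#' @param seed Integer seed.
#' @return A list: `expr` ([ExpressionMatrix-class]) and `truth_genes`
#'   (data.frame gene_id/category/cell_type).
#' @export
simulateExpression <- function(params, composition, coupled,
                               seed = .childSeed(params$rng_seed, 3L)) {
    set.seed(seed)
    nG <- params$n_genes
    T <- params$n_timepoints
    k <- length(params$cell_types)
    W <- proportions(composition)
    stopifnot(nrow(W) == T)
    gene_ids <- sprintf("gene%05d", seq_len(nG))
    nDyn <- params$n_dynamic_genes
    nCEA <- params$n_cea_genes
    nMEA <- params$n_mea_pairs
    idxDyn <- seq_len(nDyn)
    idxCEA <- seq_len(nCEA) + nDyn
    idxMEA <- seq_len(nMEA) + nDyn + nCEA

    base <- 10^stats::runif(nG, 0.3, 2.5)
    Egk <- base * exp(matrix(stats::rnorm(nG * k, 0, 0.3), nG, k))
    cea_type <- rep(NA_character_, nG)
    if (nCEA > 0) {
        drv <- sample.int(k, nCEA, replace = TRUE)
        cea_type[idxCEA] <- params$cell_types[drv]
        Egk[idxCEA, ] <- 0
        Egk[cbind(idxCEA, drv)] <- base[idxCEA] * params$cea_effect /
            params$dirichlet_base[drv]
    }
    F <- (Egk %*% t(W)) *
        exp(matrix(stats::rnorm(nG * T, 0, params$expr_noise_sd), nG, T))
    if (nDyn > 0)
        F[idxDyn, params$spike_days] <- F[idxDyn, params$spike_days,
                                          drop = FALSE] * params$dynamic_fold
    if (nMEA > 0)
        F[idxMEA, ] <- pmax(10^coupled$expr_log - 1, 0)
    dimnames(F) <- list(gene_ids, .dayLabels(T))
    category <- rep("baseline", nG)
    category[idxDyn] <- "dynamic"
    category[idxCEA] <- "cea"
    category[idxMEA] <- "mea"
    list(expr = ExpressionMatrix(F),
         truth_genes = data.frame(gene_id = gene_ids, category = category,
                                  cell_type = cea_type,
                                  stringsAsFactors = FALSE))
}

#' Simulate the methylation matrix and reference signature
#'
#' Baseline CpGs draw a stable level from a bimodal mixture (45% low mode
#' near beta 0.1, 45% high mode near 0.9, 10% uniform intermediate — the
#' typical 450K marginal shape) and add i.i.d. temporal noise
#' `N(0, meth_temporal_sd^2)`, clipped to \[0, 1\]. Signature CpGs have
#' cell-type-specific pure betas (high in their own type, low elsewhere)
#' mixed through the composition plus the same temporal noise; the pure
#' matrix is returned as the [ReferenceSignature-class]. Planted MEA CpGs
#' take the drift rows from [simulateMethylationCoupled()].
#'
#' Probe order in the matrix: planted MEA probes, then baseline, then
#' signature probes.
#'
#' @param params A [simulationParams()] list.
#' @param composition A [CompositionMatrix-class].
#' @param coupled Output of [simulateMethylationCoupled()].
#' @param seed Integer seed.
#' @return A list: `meth` ([MethylationMatrix-class]), `signature`
#'   ([ReferenceSignature-class]), and index vectors `mea_probe_ids`,
#'   `signature_probe_ids` (named list per cell type).
#' @export
simulateMethylation <- function(params, composition, coupled,
                                seed = .childSeed(params$rng_seed, 4L)) {
    set.seed(seed)
    T <- params$n_timepoints
    k <- length(params$cell_types)
    W <- proportions(composition)
    nMEA <- params$n_mea_pairs
    nSig <- params$n_signature_cpgs_per_type * k
    nBase <- params$n_cpgs - nMEA - nSig
    probe_ids <- sprintf("cpg%06d", seq_len(params$n_cpgs))
    idxMEA <- seq_len(nMEA)
    idxBase <- seq_len(nBase) + nMEA
    idxSig <- seq_len(nSig) + nMEA + nBase

    B <- matrix(0, params$n_cpgs, T)
    if (nMEA > 0) B[idxMEA, ] <- coupled$meth
    if (nBase > 0) {
        u <- stats::runif(nBase)
        level <- ifelse(u < 0.45, stats::rbeta(nBase, 5, 37),
                 ifelse(u < 0.90, stats::rbeta(nBase, 37, 5),
                        stats::runif(nBase, 0.25, 0.75)))
        B[idxBase, ] <- pmin(pmax(
            level + matrix(stats::rnorm(nBase * T, 0, params$meth_temporal_sd),
                           nBase, T), 0), 1)
    }
    sig_probe_ids <- probe_ids[idxSig]
    pure <- matrix(stats::runif(nSig * k, 0.03, 0.15), nSig, k)
    own <- rep(seq_len(k), each = params$n_signature_cpgs_per_type)
    pure[cbind(seq_len(nSig), own)] <- stats::runif(nSig, 0.75, 0.95)
    dimnames(pure) <- list(sig_probe_ids, params$cell_types)
    if (nSig > 0)
        B[idxSig, ] <- pmin(pmax(
            pure %*% t(W) +
                matrix(stats::rnorm(nSig * T, 0, params$meth_temporal_sd),
                       nSig, T), 0), 1)
    dimnames(B) <- list(probe_ids, .dayLabels(T))
    list(meth = MethylationMatrix(B),
         signature = ReferenceSignature(pure),
         mea_probe_ids = probe_ids[idxMEA],
         signature_probe_ids = split(sig_probe_ids, params$cell_types[own]))
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Runs all generator stages with deterministic child seeds and assembles
#' annotations placing genes 50 kb apart on one chromosome, each planted
#' MEA CpG within the TSS window of its gene, baseline CpGs scattered
#' uniformly (a fraction SNP-flagged), and signature CpGs on a separate
#' contig so they never enter cis pairing. A detection p-value matrix is
#' emitted in which a small fraction of baseline probes fail in one sample,
#' exercising the detection-p filter.
#'
#' @param params A [simulationParams()] list.
#' @return A list with elements `expr`, `meth`, `composition` (true),
#'   `signature`, `gene_annotation`, `cpg_annotation`, `detection_p`, and
#'   `truth` (planted composition, gene categories, MEA pairs, signature
#'   probes, and the parameters used).
#' @examples
#' d <- simulateDataset(simulationParams(n_genes = 100, n_cpgs = 400,
#'     n_dynamic_genes = 4, n_cea_genes = 4, n_mea_pairs = 4,
#'     n_signature_cpgs_per_type = 10, rng_seed = 7))
#' dim(fpkm(d$expr)); dim(betaValues(d$meth))
#' @export
simulateDataset <- function(params = simulationParams()) {
    stopifnot(inherits(params, "SimulationParams"))
    composition <- simulateComposition(params)
    coupled <- simulateMethylationCoupled(params)
    eres <- simulateExpression(params, composition, coupled)
    mres <- simulateMethylation(params, composition, coupled)

    set.seed(.childSeed(params$rng_seed, 5L))
    nG <- params$n_genes
    tss <- 50000L * seq_len(nG)
    gene_annotation <- data.frame(
        gene_id = geneIds(eres$expr), chromosome = "chr1", tss = tss,
        strand = rep_len(c("+", "-"), nG), stringsAsFactors = FALSE)

    nMEA <- params$n_mea_pairs
    k <- length(params$cell_types)
    nSig <- params$n_signature_cpgs_per_type * k
    nBase <- params$n_cpgs - nMEA - nSig
    gMEA <- params$n_dynamic_genes + params$n_cea_genes + seq_len(nMEA)
    pos_mea <- tss[gMEA] + sample(-4000:4000, nMEA, replace = TRUE)
    pos_base <- sort(sample.int(50000L * (nG + 1L), nBase))
    snp_base <- stats::runif(nBase) < params$snp_fraction
    all_ids <- probeIds(mres$meth)
    cpg_annotation <- data.frame(
        probe_id = all_ids,
        chromosome = c(rep("chr1", nMEA + nBase), rep("chrS", nSig)),
        position = c(pos_mea, pos_base, seq_len(nSig)),
        snp_overlap = c(rep(FALSE, nMEA), snp_base, rep(FALSE, nSig)),
        stringsAsFactors = FALSE)

    T <- params$n_timepoints
    detp <- matrix(stats::runif(params$n_cpgs * T, 0, 0.005),
                   params$n_cpgs, T, dimnames = list(all_ids, .dayLabels(T)))
    if (nBase > 0) {
        fail <- nMEA + which(stats::runif(nBase) < 0.01)
        if (length(fail))
            detp[cbind(fail, sample.int(T, length(fail), replace = TRUE))] <- 0.02
    }

    truth_genes <- eres$truth_genes
    mea_pairs <- data.frame(
        gene_id = truth_genes$gene_id[gMEA],
        probe_id = mres$mea_probe_ids,
        target_r2 = coupled$pairs$target_r2,
        slope = coupled$pairs$slope, stringsAsFactors = FALSE)

    list(expr = eres$expr, meth = mres$meth, composition = composition,
         signature = mres$signature, gene_annotation = gene_annotation,
         cpg_annotation = cpg_annotation, detection_p = detp,
         truth = list(
             composition = composition,
             genes = truth_genes,
             dynamic_gene_ids = truth_genes$gene_id[truth_genes$category == "dynamic"],
             cea_genes = truth_genes[truth_genes$category == "cea",
                                     c("gene_id", "cell_type")],
             mea_pairs = mea_pairs,
             signature_cpgs = mres$signature_probe_ids,
             params = params))
}

#' Write a simulated dataset to a directory of TSV files
#'
#' Emits `expression.tsv`, `methylation.tsv`, `composition.tsv`,
#' `signature.tsv`, `genes.tsv`, `cpgs.tsv`, `detection_p.tsv`, and
#' `ground_truth.tsv` (one row per planted feature: id, category,
#' parameters).
#'
#' @param dataset Output of [simulateDataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeExpressionMatrix(dataset$expr, file.path(dir, "expression.tsv"))
    writeMethylationMatrix(dataset$meth, file.path(dir, "methylation.tsv"))
    writeCompositionMatrix(dataset$composition, file.path(dir, "composition.tsv"))
    writeSignature(dataset$signature, file.path(dir, "signature.tsv"))
    writeGeneAnnotation(dataset$gene_annotation, file.path(dir, "genes.tsv"))
    writeCpGAnnotation(dataset$cpg_annotation, file.path(dir, "cpgs.tsv"))
    .writeMatrixTSV(dataset$detection_p, file.path(dir, "detection_p.tsv"),
                    "probe_id")
    tg <- dataset$truth$genes
    gt <- tg[tg$category != "baseline", ]
    mp <- dataset$truth$mea_pairs
    gt$probe_id <- mp$probe_id[match(gt$gene_id, mp$gene_id)]
    gt$target_r2 <- mp$target_r2[match(gt$gene_id, mp$gene_id)]
    utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(dir)
}
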