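test_that("simulated compositions live on the simplex with the right moments", {
    for (seed in 1:5) {
        p <- smallParams(seed)
        w <- proportions(simulateComposition(p))
        expect_true(all(abs(rowSums(w) - 1) < 1e-12))
        expect_true(all(w >= 0))
    }

    # degenerate Dirichlet: huge concentration pins every day at the base
    p <- smallParams(1, dirichlet_concentration = 1e9)
    w <- proportions(simulateComposition(p))
    expect_true(all(abs(sweep(w, 2, p$dirichlet_base)) < 1e-4))

    # Dirichlet moments: mean within 3 SE of the base proportion
    p2 <- simulationParams(n_timepoints = 10000L, n_genes = 10, n_cpgs = 50,
                           cell_types = c("A", "B"),
                           dirichlet_base = c(0.5, 0.5),
                           dirichlet_concentration = 10,
                           n_dynamic_genes = 0L, n_cea_genes = 0L,
                           n_mea_pairs = 0L, n_signature_cpgs_per_type = 5L,
                           rng_seed = 9L)
    w2 <- proportions(simulateComposition(p2))
    se <- sqrt(0.5 * 0.5 / (10 + 1)) / sqrt(10000)
    expect_lt(abs(mean(w2[, "A"]) - 0.5), 3 * se)
})

test_that("noise-free expression with fixed composition is constant per gene", {
    p <- smallParams(2, expr_noise_sd = 0, dirichlet_concentration = 1e12,
                     n_dynamic_genes = 0L, n_cea_genes = 0L, n_mea_pairs = 0L)
    comp <- simulateComposition(p)
    coup <- simulateMethylationCoupled(p)
    F <- fpkm(simulateExpression(p, comp, coup)$expr)
    cvs <- apply(F, 1, function(x) sd(x) / mean(x))
    expect_lt(max(cvs), 1e-5)
})

test_that("planted dynamic genes peak at the spike day", {
    p <- simulationParams(n_genes = 500L, n_cpgs = 700, n_dynamic_genes = 200L,
                          dynamic_fold = 4, spike_days = 12L,
                          n_cea_genes = 0L, n_mea_pairs = 0L,
                          n_signature_cpgs_per_type = 25L,
                          expr_noise_sd = 0.05, rng_seed = 5L)
    d <- simulateDataset(p)
    F <- fpkm(d$expr)[d$truth$dynamic_gene_ids, ]
    at_spike <- apply(F, 1, which.max) == 12L
    expect_gte(mean(at_spike), 0.99)
})

test_that("CEA genes track their driving cell type as noise vanishes", {
    p <- smallParams(3, expr_noise_sd = 0, n_dynamic_genes = 0L,
                     n_mea_pairs = 0L, n_cea_genes = 20L)
    comp <- simulateComposition(p)
    coup <- simulateMethylationCoupled(p)
    e <- simulateExpression(p, comp, coup)
    W <- proportions(comp)
    cea <- e$truth_genes[e$truth_genes$category == "cea", ]
    cors <- vapply(seq_len(nrow(cea)), function(i)
        cor(fpkm(e$expr)[cea$gene_id[i], ], W[, cea$cell_type[i]]), 0)
    expect_true(all(cors > 1 - 1e-10))
})

test_that("baseline methylation matches its generative scale and stays in [0,1]", {
    p0 <- smallParams(4, meth_temporal_sd = 0)
    d0 <- simulateDataset(p0)
    base_ids <- with(d0$cpg_annotation,
                     probe_id[chromosome == "chr1" &
                              !probe_id %in% d0$truth$mea_pairs$probe_id])
    sds <- apply(betaValues(d0$meth)[base_ids, ], 1, sd)
    expect_equal(max(sds), 0)

    d1 <- simulateDataset(smallParams(4))
    expect_true(all(betaValues(d1$meth) >= 0 & betaValues(d1$meth) <= 1))
})

test_that("coupled pairs hit their target R-squared", {
    # target 0: slope exactly zero
    p0 <- smallParams(6, mea_target_r2 = 0)
    c0 <- simulateMethylationCoupled(p0)
    expect_true(all(c0$pairs$slope == 0))

    # target 1 (noiseless special case): fitted R-squared is 1
    p1 <- smallParams(6, mea_target_r2 = 1)
    c1 <- simulateMethylationCoupled(p1)
    r2 <- vapply(seq_len(nrow(c1$meth)), function(i)
        cor(c1$expr_log[i, ], c1$meth[i, ])^2, 0)
    expect_true(all(r2 > 1 - 1e-9))

    # target 0.5: mean fitted R2 matches an independent Monte-Carlo oracle
    # for the sampling expectation of R^2 at n = 24
    set.seed(99)
    oracle <- mean(replicate(2000, {
        x <- rnorm(24)
        y <- x + rnorm(24, 0, sd(x) * 1)   # population R2 = 0.5
        cor(x, y)^2
    }))
    ph <- simulationParams(n_timepoints = 24L, n_genes = 1000L, n_cpgs = 1100L,
                           n_dynamic_genes = 0L, n_cea_genes = 0L,
                           n_mea_pairs = 1000L, mea_target_r2 = 0.5,
                           n_signature_cpgs_per_type = 10L, rng_seed = 7L)
    ch <- simulateMethylationCoupled(ph)
    fitted <- vapply(seq_len(1000), function(i)
        cor(ch$expr_log[i, ], ch$meth[i, ])^2, 0)
    expect_lt(abs(mean(fitted) - oracle), 0.05)
})

test_that("datasets are reproducible and planted categories disjoint", {
    a <- simulateDataset(smallParams(8))
    b <- simulateDataset(smallParams(8))
    expect_identical(fpkm(a$expr), fpkm(b$expr))
    expect_identical(betaValues(a$meth), betaValues(b$meth))
    expect_identical(a$cpg_annotation, b$cpg_annotation)

    tg <- a$truth$genes
    expect_identical(anyDuplicated(tg$gene_id), 0L)
    expect_identical(sum(tg$category == "dynamic"), 8L)
    expect_identical(sum(tg$category == "cea"), 8L)
    expect_identical(sum(tg$category == "mea"), 8L)
    # every planted id exists in the matrices
    expect_true(all(a$truth$mea_pairs$probe_id %in% probeIds(a$meth)))
    expect_true(all(tg$gene_id %in% geneIds(a$expr)))

    # a different seed changes the data
    c <- simulateDataset(smallParams(9))
    expect_false(identical(fpkm(a$expr), fpkm(c$expr)))
})

test_that("writeDataset emits readable TSVs with ground truth", {
    d <- simulateDataset(smallParams(10))
    dir <- withr::local_tempdir()
    writeDataset(d, dir)
    expect_equal(fpkm(readExpressionMatrix(file.path(dir, "expression.tsv"))),
                 fpkm(d$expr))
    expect_equal(betaValues(readMethylationMatrix(file.path(dir, "methylation.tsv"))),
                 betaValues(d$meth))
    gt <- read.delim(file.path(dir, "ground_truth.tsv"))
    expect_setequal(gt$category, c("dynamic", "cea", "mea"))
    sig <- readSignature(file.path(dir, "signature.tsv"))
    expect_identical(cellTypes(sig), d$truth$params$cell_types)
})
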