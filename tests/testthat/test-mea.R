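test_that("pair extraction honours the inclusive window and SNP exclusion", {
    g <- data.frame(gene_id = "g1", chromosome = "chr1", tss = 10000L,
                    strand = "+", stringsAsFactors = FALSE)
    p <- data.frame(probe_id = c("in_edge", "out_edge", "snp"),
                    chromosome = "chr1",
                    position = c(15000L, 15001L, 10100L),
                    snp_overlap = c(FALSE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
    pairs <- suppressMessages(extractPairs(g, p, 5000L))
    expect_identical(pairs$probe_id, "in_edge")
    expect_identical(pairs$tss_distance, 5000L)
})

test_that("pair extraction equals a brute-force all-pairs distance scan", {
    for (seed in 1:5) {
        set.seed(seed)
        nG <- 30; nC <- 200
        g <- data.frame(gene_id = sprintf("g%02d", 1:nG),
                        chromosome = sample(c("chr1", "chr2"), nG, TRUE),
                        tss = sample.int(200000L, nG),
                        strand = sample(c("+", "-"), nG, TRUE),
                        stringsAsFactors = FALSE)
        p <- data.frame(probe_id = sprintf("c%03d", 1:nC),
                        chromosome = sample(c("chr1", "chr2"), nC, TRUE),
                        position = sample.int(200000L, nC),
                        snp_overlap = runif(nC) < 0.1,
                        stringsAsFactors = FALSE)
        got <- suppressMessages(extractPairs(g, p, 5000L))
        brute <- do.call(rbind, lapply(1:nG, function(i) {
            ok <- !p$snp_overlap & p$chromosome == g$chromosome[i] &
                abs(p$position - g$tss[i]) <= 5000L
            if (!any(ok)) return(NULL)
            data.frame(gene_id = g$gene_id[i], probe_id = p$probe_id[ok],
                       tss_distance = as.integer(
                           (p$position[ok] - g$tss[i]) *
                           ifelse(g$strand[i] == "+", 1L, -1L)),
                       stringsAsFactors = FALSE)
        }))
        key <- function(df) sort(paste(df$gene_id, df$probe_id, df$tss_distance))
        expect_identical(key(got), key(brute))
    }
})

test_that("the reference-day transform rescales and guards against zero", {
    expect_equal(relativeToReference(c(2, 4, 1)), c(1, 2, 0.5))
    set.seed(1)
    x <- rexp(10) + 1
    expect_identical(relativeToReference(x, ref_index = 4)[4], 1)
    expect_null(relativeToReference(c(0, 1, 2)))
    expect_null(relativeToReference(c(1e-9, 1, 2)))
    expect_error(relativeToReference(1:3, ref_index = 5), "ref_index")
})

test_that("Model-1 R2 is the squared Pearson correlation", {
    m <- c(0.9, 1.1, 1.0, 1.3, 0.8)
    e <- 3 + 2 * m
    f <- meaModel1(e, m)
    expect_equal(f$r2, 1)
    expect_equal(f$beta_m, 2)
    expect_equal(f$intercept, 3)

    for (seed in 1:10) {
        set.seed(seed)
        e <- rnorm(24); m <- rnorm(24)
        expect_equal(meaModel1(e, m)$r2, cor(e, m)^2, tolerance = 1e-12)
    }
    expect_equal(meaModel1(rnorm(10), rep(1, 10))$r2, 0)
    expect_equal(meaModel1(rep(1, 10), rnorm(10))$r2, 0)
})

test_that("Model 2 reduces to Model 1 and adjusts composition away", {
    set.seed(2)
    e <- rnorm(24); m <- rnorm(24)
    m2 <- meaModel2(e, m, rep(0.3, 24))
    expect_equal(m2$r2_meth, meaModel1(e, m)$r2, tolerance = 1e-10)

    # expression fully driven by composition: methylation gets ~ nothing.
    # The null 95th percentile of R2 at n = 24 is qbeta(.95, .5, 11) ~ 0.16
    set.seed(3)
    ct <- rnorm(24)
    hits <- vapply(1:50, function(i) {
        mm <- rnorm(24)
        meaModel2(2 * ct + rnorm(24, 0, 1e-8), mm, ct)$r2_meth
    }, 0)
    expect_lt(median(hits), qbeta(0.95, 0.5, 11))

    # invariant to positive rescaling of the methylation series
    a <- meaModel2(e, m, ct)
    b <- meaModel2(e, 100 * m, ct)
    expect_equal(a$r2_meth, b$r2_meth, tolerance = 1e-10)

    # collinear predictors are flagged
    expect_true(meaModel2(e, m, 2 * m)$degenerate)
})

test_that("Spearman rho matches rank-then-Pearson and permutation p is bounded", {
    for (seed in 1:10) {
        set.seed(seed)
        e <- sample(1:8, 24, replace = TRUE)   # plenty of ties
        m <- sample(1:8, 24, replace = TRUE)
        got <- spearmanPermutation(e, m, B = 10)
        expect_equal(got$rho, cor(rank(e), rank(m)), tolerance = 1e-12)
        expect_gte(got$perm_p, 1 / 11)
        expect_lte(got$perm_p, 1)
    }

    # perfectly monotone pair: rho = 1, p at (or near) the add-one floor
    x <- 1:12
    res <- spearmanPermutation(x, x^3, B = 1000, seed = 7)
    expect_equal(res$rho, 1)
    expect_lte(res$perm_p, 3 / 1001)

    # deterministic given seed
    set.seed(4)
    e <- rnorm(24); m <- rnorm(24)
    a <- spearmanPermutation(e, m, B = 200, seed = 42)
    b <- spearmanPermutation(e, m, B = 200, seed = 42)
    expect_identical(a$perm_p, b$perm_p)

    d <- spearmanPermutation(rep(1, 10), rnorm(10), B = 10)
    expect_true(d$degenerate)
    expect_identical(d$perm_p, 1)
})

test_that("methylationSD is the sample SD of the raw beta series", {
    expect_equal(methylationSD(c(0.1, 0.3)), sqrt(0.02), tolerance = 1e-7)
    expect_identical(methylationSD(rep(0.5, 24)), 0)
    expect_error(methylationSD(0.2), "length")
})

test_that("distribution comparison matches a brute-force U count", {
    x <- c(1, 1, 2, 5); y <- c(1, 3, 4)
    got <- compareDistributions(x, y)
    bruteU <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(unname(got$statistic), bruteU)

    for (seed in 1:5) {
        set.seed(seed)
        a <- sample(1:10, sample(5:20, 1), replace = TRUE)
        b <- sample(1:10, sample(5:20, 1), replace = TRUE)
        got <- compareDistributions(a, b)
        expect_equal(unname(got$statistic),
                     sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "==")))
    }

    same <- compareDistributions(1:10, 1:10)
    expect_equal(same$p_value, 1)
    expect_true(compareDistributions(1, 1:5)$insufficient)
    expect_error(compareDistributions(numeric(0), 1), "nonempty")
})

test_that("runMEA stratification drops exactly the CEA-gene pairs", {
    d <- simulateDataset(smallParams(16))
    cfg <- runConfig(n_permutations = 50)
    comp <- suppressMessages(estimateComposition(d$meth, d$signature))
    dyn <- suppressMessages(detectDynamicGenes(d$expr, cfg))
    cea <- suppressMessages(ceaAnalysis(d$expr, comp, cfg))
    pairs <- suppressMessages(extractPairs(d$gene_annotation, d$cpg_annotation))

    strat <- suppressMessages(runMEA(d$expr, d$meth, pairs, cea, dyn,
                                     composition = comp, config = cfg))
    cea_genes <- cea$gene_id[cea$is_cea]
    expect_false(any(strat$results$gene_id %in% cea_genes))

    cfg2 <- runConfig(n_permutations = 50, stratify_cea = FALSE)
    full <- suppressMessages(runMEA(d$expr, d$meth, pairs, cea, dyn,
                                    composition = comp, config = cfg2))
    kept_key <- paste(strat$results$gene_id, strat$results$probe_id)
    full_key <- paste(full$results$gene_id, full$results$probe_id)
    non_cea_key <- full_key[!full$results$gene_id %in% cea_genes]
    expect_setequal(kept_key, non_cea_key)

    r <- strat$results
    expect_true(all(r$r2_model1 >= 0 & r$r2_model1 <= 1))
    expect_true(all(r$perm_p >= 1 / 51 & r$perm_p <= 1))
    expect_true(all(r$meth_sd >= 0))
    expect_true(all(r$gene_class %in%
        c("dynamic/non-CEA", "non-dynamic/non-CEA")))
})
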