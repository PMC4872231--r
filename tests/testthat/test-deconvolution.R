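## A random full-rank signature plus samples mixed from known proportions.
makeSignature <- function(nPerType = 20, types = c("A", "B", "C", "D"),
                          seed = 1) {
    set.seed(seed)
    k <- length(types)
    n <- nPerType * k
    S <- matrix(runif(n * k, 0.03, 0.15), n, k)
    own <- rep(seq_len(k), each = nPerType)
    S[cbind(seq_len(n), own)] <- runif(n, 0.75, 0.95)
    dimnames(S) <- list(sprintf("sig%03d", seq_len(n)), types)
    ReferenceSignature(S)
}

mixSamples <- function(sig, Wtrue, noise_sd = 0, seed = 1) {
    set.seed(seed)
    M <- sig@values %*% t(Wtrue)
    M <- pmin(pmax(M + matrix(rnorm(length(M), 0, noise_sd), nrow(M)), 0), 1)
    rownames(M) <- probeIds(sig)
    colnames(M) <- rownames(Wtrue)
    MethylationMatrix(M)
}

test_that("noiseless mixtures are recovered exactly", {
    sig <- makeSignature()
    Wtrue <- t(vapply(1:6, function(i) simplexVector(4, seed = i), numeric(4)))
    dimnames(Wtrue) <- list(sprintf("Day%d", 1:6), cellTypes(sig))
    meth <- mixSamples(sig, Wtrue)
    est <- suppressMessages(estimateComposition(meth, sig))
    expect_lt(max(abs(proportions(est) - Wtrue)), 1e-8)
})

test_that("a pure sample projects onto its single cell type", {
    sig <- makeSignature(seed = 2)
    W <- matrix(0, 3, 4, dimnames = list(sprintf("Day%d", 1:3), cellTypes(sig)))
    W[, "B"] <- 1
    est <- suppressMessages(estimateComposition(mixSamples(sig, W), sig))
    expect_lt(max(abs(proportions(est) - W)), 1e-8)
})

test_that("probe order does not change the solution", {
    sig <- makeSignature(seed = 3)
    Wtrue <- t(vapply(1:4, function(i) simplexVector(4, seed = 10 + i),
                      numeric(4)))
    dimnames(Wtrue) <- list(sprintf("Day%d", 1:4), cellTypes(sig))
    meth <- mixSamples(sig, Wtrue, noise_sd = 0.01, seed = 5)
    est1 <- suppressMessages(estimateComposition(meth, sig))
    set.seed(6)
    perm <- sample(nrow(meth))
    meth2 <- MethylationMatrix(betaValues(meth)[perm, ])
    est2 <- suppressMessages(estimateComposition(meth2, sig))
    expect_equal(proportions(est1), proportions(est2), tolerance = 1e-10)
})

test_that("recovery error grows continuously with noise", {
    sig <- makeSignature(seed = 4)
    Wtrue <- t(vapply(1:10, function(i) simplexVector(4, seed = 20 + i),
                      numeric(4)))
    dimnames(Wtrue) <- list(sprintf("Day%d", 1:10), cellTypes(sig))
    maes <- vapply(c(0, 0.01, 0.05, 0.15), function(s) {
        est <- suppressMessages(
            estimateComposition(mixSamples(sig, Wtrue, s, seed = 7), sig))
        mean(abs(proportions(est) - Wtrue))
    }, 0)
    expect_true(all(diff(maes) > 0))
})

test_that("constrained solution beats any single-type projection", {
    sig <- makeSignature(seed = 5)
    S <- sig@values
    Wtrue <- t(vapply(1:5, function(i) simplexVector(4, seed = 30 + i),
                      numeric(4)))
    dimnames(Wtrue) <- list(sprintf("Day%d", 1:5), cellTypes(sig))
    meth <- mixSamples(sig, Wtrue, noise_sd = 0.03, seed = 8)
    est <- proportions(suppressMessages(estimateComposition(meth, sig)))
    M <- betaValues(meth)
    for (t in 1:5) {
        rss_fit <- sum((S %*% est[t, ] - M[, t])^2)
        rss_single <- min(vapply(1:4, function(k) {
            w <- sum(S[, k] * M[, t]) / sum(S[, k]^2)  # 1-type least squares
            sum((S[, k] * max(w, 0) - M[, t])^2)
        }, 0))
        expect_lte(rss_fit, rss_single + 1e-12)
    }
})

test_that("signature problems are reported as errors", {
    sig <- makeSignature(seed = 6)
    Wtrue <- matrix(simplexVector(4, 40), 1, 4,
                    dimnames = list("Day1", cellTypes(sig)))
    meth <- mixSamples(sig, Wtrue)
    # < 90% probe overlap
    meth_sub <- MethylationMatrix(betaValues(meth)[1:60, , drop = FALSE])
    expect_error(estimateComposition(meth_sub, sig), "90%")
    # duplicated cell-type column makes the signature rank-deficient
    S <- sig@values
    Sdup <- cbind(S, E = S[, "D"])
    expect_error(ReferenceSignature(Sdup), "rank")
})

test_that("normalization rescales proportions to unit sum", {
    sig <- makeSignature(seed = 7)
    Wtrue <- t(vapply(1:3, function(i) 0.8 * simplexVector(4, seed = 50 + i),
                      numeric(4)))
    dimnames(Wtrue) <- list(sprintf("Day%d", 1:3), cellTypes(sig))
    meth <- mixSamples(sig, Wtrue)
    est <- suppressMessages(estimateComposition(meth, sig, normalize = TRUE))
    expect_true(all(abs(rowSums(proportions(est)) - 1) < 1e-8))
})

test_that("compositionQC summarizes sums and per-type moments", {
    W <- rbind(Day1 = c(A = 0.5, B = 0.5), Day2 = c(A = 0.3, B = 0.2))
    qc <- suppressMessages(compositionQC(CompositionMatrix(W)))
    expect_equal(qc$sample_summary$flagged, c(FALSE, TRUE))
    expect_equal(qc$type_summary$mean, unname(colMeans(W)))
    expect_equal(qc$type_summary$sd, unname(apply(W, 2, sd)))
})
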