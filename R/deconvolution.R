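## Reference-based cell-type deconvolution: per-sample constrained
## projection of the signature-probe betas onto the signature matrix.

#' Estimate cell-type composition from methylation
#'
#' For each sample t, solves the non-negative least-squares problem
#' `min_w || S w - m_t ||^2, w >= 0`, where `S` is the reference signature
#' restricted to the probes present in the data and `m_t` the sample's
#' betas at those probes — the constrained-projection estimator standard
#' for blood methylation deconvolution. The Lawson-Hanson active-set
#' solver ([pracma::lsqnonneg()]) gives the exact optimum of this convex
#' problem. The raw projection does not force proportions to sum to one;
#' `normalize = TRUE` rescales each sample's vector to unit sum when its
#' raw sum is positive.
#'
#' @param meth A [MethylationMatrix-class] containing (at least 90% of)
#'   the signature probes.
#' @param signature A [ReferenceSignature-class].
#' @param normalize Rescale proportions to sum to 1 per sample.
#'   Default FALSE.
#' @return A [CompositionMatrix-class], samples x cell types.
#' @examples
#' p <- simulationParams(n_genes = 50, n_cpgs = 300, n_dynamic_genes = 0,
#'     n_cea_genes = 0, n_mea_pairs = 0, n_signature_cpgs_per_type = 50,
#'     rng_seed = 3)
#' d <- simulateDataset(p)
#' est <- estimateComposition(d$meth, d$signature)
#' head(proportions(est))
#' @export
estimateComposition <- function(meth, signature, normalize = FALSE) {
    stopifnot(is(meth, "MethylationMatrix"), is(signature, "ReferenceSignature"))
    S_full <- signature@values
    shared <- intersect(rownames(S_full), probeIds(meth))
    if (length(shared) < 0.9 * nrow(S_full))
        stop(sprintf("only %d of %d signature probes present in the data (>= 90%% required)",
             length(shared), nrow(S_full)), call. = FALSE)
    S <- S_full[shared, , drop = FALSE]
    if (qr(S)$rank < ncol(S)) {
        qrS <- qr(S)
        dep <- colnames(S)[qrS$pivot[-seq_len(qrS$rank)]]
        stop("signature is rank-deficient on the available probes; dependent cell types: ",
             paste(dep, collapse = ", "), call. = FALSE)
    }
    M <- betaValues(meth)[shared, , drop = FALSE]
    W <- t(apply(M, 2L, function(m) pracma::lsqnonneg(S, m)$x))
    dimnames(W) <- list(sampleIds(meth), colnames(S))
    if (normalize) {
        s <- rowSums(W)
        pos <- s > 0
        W[pos, ] <- W[pos, , drop = FALSE] / s[pos]
    }
    .mdLog("estimateComposition: %d samples x %d cell types from %d signature probes (normalize=%s)",
           nrow(W), ncol(W), length(shared), normalize)
    CompositionMatrix(W)
}

#' Composition quality-control report
#'
#' Per-sample proportion sums with flags for sums outside \[0.8, 1.2\]
#' (the raw projection should land near the simplex; large deviations
#' indicate a poor signature match), and the per-type mean and SD summary
#' used to describe estimated compositions over a time course.
#'
#' @param comp A [CompositionMatrix-class].
#' @return A list: `sample_summary` (data.frame sample_id/sum/flagged) and
#'   `type_summary` (data.frame cell_type/mean/sd).
#' @export
compositionQC <- function(comp) {
    stopifnot(is(comp, "CompositionMatrix"))
    W <- proportions(comp)
    s <- rowSums(W)
    sample_summary <- data.frame(
        sample_id = rownames(W), sum = unname(s),
        flagged = unname(s < 0.8 | s > 1.2), stringsAsFactors = FALSE)
    type_summary <- data.frame(
        cell_type = colnames(W),
        mean = unname(colMeans(W)),
        sd = unname(apply(W, 2L, stats::sd)), stringsAsFactors = FALSE)
    if (any(sample_summary$flagged))
        .mdLog("compositionQC: %d sample(s) with proportion sum outside [0.8, 1.2]",
               sum(sample_summary$flagged))
    list(sample_summary = sample_summary, type_summary = type_summary)
}
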