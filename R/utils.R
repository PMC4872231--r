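## Internal helpers shared across pipeline stages.

.mdLog <- function(fmt, ...) {
    message(sprintf(paste0("[methdyn] ", fmt), ...))
    invisible(NULL)
}

## Deterministic child seed for a pipeline stage, kept inside 32-bit range.
.childSeed <- function(seed, stage) {
    (as.integer(seed) %% 1000003L) * 1009L + stage * 7919L
}

.assertAligned <- function(expr, meth) {
    if (!identical(sampleIds(expr), sampleIds(meth)))
        stop("expression and methylation matrices are not sample-aligned; ",
             "run alignSamples() first", call. = FALSE)
    invisible(TRUE)
}

## sample SD (n-1 denominator); base sd() already does this, kept for intent
.sampleSD <- function(x) stats::sd(x)
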