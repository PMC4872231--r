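# methdyn

Does day-to-day variation in DNA methylation explain short-term gene
expression dynamics within a single individual? `methdyn` implements the
complete longitudinal analysis for paired transcriptome (FPKM) and
methylome (Illumina-array beta value) time courses from mixed cell
populations such as blood: it separates genuine regulatory signal from
cell-composition shifts, identifies dynamically expressed genes, and
quantifies how much of their expression variance cis CpG methylation can
account for. A synthetic-data generator with planted ground truth makes
every inference stage verifiable without access to protected human data.

## The analysis

Given a genes × timepoints FPKM matrix and a CpG-probes × timepoints beta
matrix over the same days:

1. **Cell-type deconvolution.** For each sample *t*, the composition
   *w<sub>t</sub>* is estimated from signature-CpG betas by constrained
   projection — minimize ‖*S w* − *m<sub>t</sub>*‖² subject to *w* ≥ 0,
   with *S* the reference signature (mean betas of discriminating CpGs in
   purified leukocyte populations). Solved exactly by Lawson–Hanson NNLS.
2. **Dynamic genes.** Each gene's mean of log₁₀(FPKM+1) assigns it to a
   0.05-wide bin; within each bin, coefficient-of-variation outliers are
   flagged by the iterative Smirnov–Grubbs test
   (*G* = (max *x* − mean *x*)/sd *x* against the *t*-derived critical
   value at α/N) and defined as dynamically expressed.
3. **CEA (composition/expression association).** Per gene, the nested
   linear models M1: *E<sub>t</sub>* = β₀ + Σ<sub>c</sub> β<sub>c</sub>
   *P<sub>ct</sub>* and M0: *E<sub>t</sub>* = β₀ are compared by ANOVA
   F-test (rank-aware, since proportions sum to ~1); genes with p < 0.05
   are composition-associated and removed from the methylation analysis.
4. **MEA (methylation/expression association).** Genes are paired with
   non-SNP CpGs within 5,000 bp of the TSS. Expression (log₁₀(FPKM+1))
   and methylation (beta) are converted to Day-1-relative values; Model 1
   regresses *E<sub>t</sub>* on *M<sub>t</sub>* (R² = squared Pearson
   correlation), Model 2 adds the best CEA cell type's proportion and
   reports the composition-adjusted partial R²; significance comes from a
   permutation test on the Spearman correlation (1,000 shuffles of the
   expression vector, add-one corrected). Per-CpG temporal SDs and the
   dynamic vs non-dynamic distribution comparisons (Mann–Whitney U)
   complete the report.

## Worked example

```r
library(methdyn)
params  <- simulationParams(n_genes = 1000, n_cpgs = 4000,
                            n_dynamic_genes = 20, n_cea_genes = 30,
                            n_mea_pairs = 15, rng_seed = 7)
dataset <- simulateDataset(params)
out     <- runPipeline(dataset, runConfig(n_permutations = 500, rng_seed = 7))
out$stratification$table
```

```
[methdyn] detection-p filter (< 0.01 in all 24 samples): 3962 / 4000 probes retained
[methdyn] estimateComposition: 24 samples x 6 cell types from 600 signature probes (normalize=FALSE)
[methdyn] detectDynamicGenes: 63 of 1000 genes dynamic (6.3%)
[methdyn] ceaAnalysis: 198 of 1000 genes CEA at p < 0.05
[methdyn] extractPairs: 654 gene-CpG pairs within 5000 bp of a TSS
[methdyn] runMEA: 518 pairs analysed; median Model-1 R2 = 0.021; 7.7% of pairs at perm p < 0.05

            CEA non-CEA
dynamic      29      34
non-dynamic 169     768
```

The 2×2 table cross-classifies the gene universe by dynamic-expression
and composition-association status. Of the gene–CpG pairs surviving CEA
exclusion, the median Model-1 R² is 0.021 — i.e. cis methylation explains
about 2% of the expression variance of a typical non-planted gene, which
for 24 timepoints is what pure noise produces — while the planted
methylation-driven pairs are picked up by the permutation test (7.7% of
pairs significant against a 5% null rate). The estimated compositions
recover the simulated leukocyte panel:

```r
out$composition_qc$type_summary
#>   cell_type       mean         sd
#> 1      CD8T 0.10003521 0.02349929
#> 2      CD4T 0.14584179 0.02915589
#> 3        NK 0.04248509 0.01561408
#> 4     Bcell 0.05679898 0.02516181
#> 5      Mono 0.09642303 0.02967763
#> 6      Gran 0.55818139 0.03947931
```

A command-line front end covering all stages
(`simulate | deconvolve | dynamic | cea | mea | run-all`) is in
`inst/scripts/methdyn.R`; file formats are plain TSV (see
`?readExpressionMatrix`, `?readGeneAnnotation`).

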