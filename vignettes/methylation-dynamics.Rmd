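---
title: "Methods: intraindividual methylation stability and expression dynamics"
author: "methdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intraindividual methylation stability and expression dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdyn)
```

# The question and the design

Short-term ("dynamic") changes in gene expression within one person —
responses to infection, inflammation, diet — could in principle be driven
by equally short-term changes in DNA methylation at nearby CpG sites. The
design this package analyses is a dense within-individual time course:
the same tissue sampled on ~24 consecutive days, profiled for both the
transcriptome (FPKM) and the methylome (array beta values). Because the
sampled tissue (blood, PBMC) is a mixture of cell types whose proportions
drift from day to day, the central confounder is cell composition: a
gene expressed mainly in monocytes will track the monocyte fraction, and
so will the methylation of cell-type-specific CpGs, producing spurious
methylation–expression correlations. The pipeline therefore (i) estimates
composition from the methylome itself, (ii) finds dynamically expressed
genes, (iii) removes composition-associated genes, and only then
(iv) asks how much expression variance cis methylation explains.

# Stage models and assumptions

## Deconvolution

Composition is estimated per sample by non-negative least squares against
a reference signature of cell-type-discriminating CpGs (high beta in the
owning type, low elsewhere): $\hat w_t = \arg\min_{w \ge 0} \lVert S w -
m_t \rVert^2$. This is the standard constrained-projection estimator for
blood methylation. We deliberately do not impose $\sum_k w_k = 1$ during
optimization — the raw projection's sum is itself a QC signal
(`compositionQC()` flags samples outside [0.8, 1.2]) — and offer unit-sum
rescaling as a post-hoc option (`normalize_composition`, default off;
logged so both variants are reproducible). Signature construction from
sorted-cell reference panels is out of scope: the signature is an input,
and the generator emits one. The active-set NNLS solver is exact for this
convex problem, so noiseless mixtures are recovered to solver tolerance
(~1e-10), and recovery error grows continuously with beta noise.

## Dynamic genes

The dispersion measure is the coefficient of variation, sample SD over
mean. CV depends strongly on expression level, so genes are compared only
within bins of their mean log10(FPKM+1), `bin_width = 0.05`, bins
left-closed right-open (a mean of exactly 0.05 is in bin 1). Within a
bin, CV outliers are flagged by the Smirnov–Grubbs test: at each pass
$G = (\max x - \bar x)/s$ is compared with
$G_{crit} = \frac{N-1}{\sqrt N}\sqrt{\frac{t^2}{N-2+t^2}}$, $t$ the upper
$\alpha/N$ Student-t quantile on $N-2$ df; the maximum is removed and the
test repeated until no rejection (the usual iterative reading of
"Smirnov–Grubbs"; a single-pass variant is available via
`grubbs_iterate = FALSE`).

Choices that the underlying procedure leaves open, and how we fixed them:

* **CV scale** — raw FPKM or log10(FPKM+1) is not dictated by the
  procedure; we default to the log scale (`cv_scale = "log"`) because it
  is the binning axis, and expose `"raw"`.
* **Sidedness** — only unusually *high* CVs mean "dynamic"; the test is
  one-sided upper by default.
* **α** — 0.05 per pass (`grubbs_alpha`), configurable.
* **Degenerate input** — genes with zero mean on the analysis scale have
  no CV and are excluded before binning, logged; bins smaller than
  `min_bin_size = 3` are skipped; ties at the bin maximum resolve to the
  lexicographically first gene id, making results order-independent.

## CEA

Per gene, log10(FPKM+1) is regressed on an intercept plus all cell-type
proportions (M1) and compared with the intercept-only null (M0) by the
ANOVA F-test, $F = \frac{(RSS_0 - RSS_1)/q}{RSS_1/(n - r_1)}$ with
$q = r_1 - 1$. Because proportions sum to ~1 the M1 design is
near-collinear with the intercept; we fit through rank-revealing QR and
take $r_1$ as the design rank, which matches the ANOVA semantics exactly
and makes the test invariant to duplicated or redundant composition
columns (an equivalent drop-one-column parameterization would give the
identical F). A constant expression series has nothing to explain and is
reported as F = 0, p = 1. No multiple-testing correction is applied by
default — the stratification uses raw p < 0.05 — with optional BH
adjustment (`adjust = "BH"`).

The downstream composition covariate ("the cell type with the lowest CEA
p") is ambiguous when the CEA test is joint over all types; we interpret
it as the type whose *univariate* regression p-value is smallest, computed
alongside the joint test, and carry it into MEA Model 2. This is an
operationalization choice, documented rather than hidden.

## MEA

Genes are paired with all same-chromosome CpGs within
`tss_window_bp = 5000` bases of the TSS, inclusive on both ends;
SNP-overlapping probes are excluded first. The reported TSS distance is
strand-adjusted, but the window filter uses absolute distance. Because
FPKM and beta are incommensurable ratios, both series are divided by
their Day-1 value before regression (`reference_day_index = 1`); a
reference value below `min_ref = 1e-6` would amplify noise without bound,
so such series are excluded with a logged reason — we rejected
pseudo-count repair as inventing data.

Model 1 is simple regression of relative expression on relative
methylation; its R² is identically the squared Pearson correlation (a
tested invariant). Model 2 adds the best CEA type's proportion series;
its methylation R² is the squared correlation between the
composition-adjusted partial residual $E - \hat\beta_0 - \hat\beta_{CT}
CT$ and $\hat\beta_m M$ — the partial-R² reading; a plain joint-model R²
is available via `model2_partial = FALSE`. When the covariate is constant
Model 2 provably reduces to Model 1. Collinear designs are fitted by
pseudo-inverse and flagged, because the attribution of variance between
collinear predictors is not unique.

Significance per pair comes from a permutation test of the Spearman rank
correlation: `n_permutations = 1000` uniform shuffles of the expression
vector, $p = (1 + \#\{|\rho_b| \ge |\rho_{obs}|\})/(B+1)$. The add-one
correction keeps p off zero (floor $1/(B+1)$); two-sided on $|\rho|$ by
default (`perm_two_sided`), since the direction of a cis effect is not
prespecified. Per-CpG methylation SD is computed on the raw beta scale
(not Day-1-relative), matching its role as an absolute stability measure.

By default, pairs at CEA genes are removed before the per-pair analysis
(`stratify_cea = TRUE`); the alternative — keep all genes and rely on
Model-2 adjustment — is supported and reachable via config, as both
variants are legitimate readings of the procedure. The dynamic vs
non-dynamic distribution comparison uses the two-sided Mann–Whitney U
test with tie correction (medians and IQRs are the natural accompanying
summaries); Kolmogorov–Smirnov is available via `dist_test = "ks"`, since
no particular two-sample test is canonical here.

# The synthetic-data generator

The generator produces the full input surface — expression, methylation,
signature, annotations, detection p-values — with planted, recorded
structure, under conditions chosen to emulate the motivating study
design:

* **24 timepoints, 6 leukocyte types** (CD8T, CD4T, NK, B cell,
  monocyte, granulocyte; labels only). Composition is Dirichlet around a
  typical whole-blood panel (granulocytes 55%, CD4T 15%, ...), with
  concentration 150, giving day-to-day per-type SDs of 2–4 percentage
  points — stable but estimable, the regime the deconvolution figures of
  such studies display.
* **Expression** mixes log-normal cell-type-specific levels through the
  composition with multiplicative log-normal noise (`expr_noise_sd =
  0.05`); per-gene base levels spread mean log10(FPKM+1) over ~0.3–2.5 so
  the 0.05-wide bins are well populated at 5,000 genes.
* **Dynamic genes** get a multiplicative fold-4 spike at a single
  mid-series day, mimicking a transient inflammatory episode;
  multiplicative (not additive) because detection operates on the log
  scale and observed responses are fold-change-like.
* **Methylation** baseline betas come from a bimodal mixture (45% low
  mode ≈ 0.1, 45% high mode ≈ 0.9, 10% uniform intermediate — the typical
  450K marginal), with i.i.d. temporal noise `meth_temporal_sd = 0.01`,
  matching the observed intraindividual stability scale (median per-CpG
  SD ≈ 0.01 at n = 24; an automated test checks the generated median
  lands in [0.008, 0.012]).
* **Planted MEA pairs** couple log expression linearly to a slow
  sinusoidal methylation drift; the noise variance is set conditional on
  the realized drift so the population R² equals `mea_target_r2`
  exactly (0.5 by default).
* Planted gene categories are disjoint by construction; all randomness
  flows from one master seed via deterministic per-stage child seeds, so
  identical parameters give bit-identical datasets.

What the generator does **not** emulate: probe-level intensity artifacts
and normalization residue, batch effects, autocorrelated biological
noise, interindividual variation (the design is strictly
intraindividual), genuine genomic CpG density (annotations place genes
50 kb apart with CpGs scattered uniformly; signature CpGs sit on a
separate contig so they never enter cis pairing). Passing recovery tests
on this generator therefore demonstrates the statistical machinery is
correct and calibrated — not that real arrays meet these assumptions.

# Numerical choices and verification scales

* Grubbs critical values are verified against numerical inversion of the
  t-tail probability to 1e-8 over N = 3..200.
* CEA F and p are verified against explicit projection-matrix algebra to
  1e-10; null calibration is checked on 10,000 simulated null genes
  (fraction of p < 0.05 inside the 99% binomial CI of 0.05).
* Permutation p-values are checked for null uniformity on 10,000
  independent pairs at B = 1000 (KS test), and bounded in
  $[1/(B+1), 1]$ by construction.
* End-to-end recovery runs the default study scale — 5,000 genes, 20,000
  CpGs, 24 timepoints — and requires dynamic-gene sensitivity ≥ 0.8,
  ≥ 90% CEA recovery, ≥ 80% MEA power with ~5% null positives. These
  problem sizes keep the full verification suite to a few minutes while
  leaving each estimate's Monte-Carlo error far below the margins being
  asserted.
* An optional minimum-mean-FPKM expression filter exists
  (`min_mean_fpkm`), default off: the analysed gene universe is taken as
  given rather than silently re-filtered.

# Known limitations

* The 24 timepoints are treated as exchangeable observations; no
  autocorrelation or time-series structure is modelled, in either the
  tests or the generator. With strong temporal autocorrelation the
  permutation null (which destroys ordering) would be anticonservative.
* Only cis (TSS-window) pairs are considered; distal regulation,
  region-level smoothing and mediation analysis are out of scope.
* The deconvolution is only as good as the supplied signature; the
  package validates rank and probe overlap but cannot detect a
  biologically wrong reference.
* Raw p < 0.05 accounting follows the original analysis; for discovery
  use, enable the BH options.

```{r session}
sessionInfo()
```
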