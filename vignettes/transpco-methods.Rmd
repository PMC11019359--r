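---
title: "Mapping trans-eQTLs of gene modules with a PC-based omnibus test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping trans-eQTLs of gene modules with a PC-based omnibus test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transpco)
```

## The problem

Trans-acting regulatory variants typically perturb many genes at once — a
variant near a transcription factor shifts the whole downstream program —
but each individual gene moves only slightly. Single-gene tests therefore
face a double penalty: tiny per-gene effects and a genome-times-transcriptome
multiple-testing burden. Testing a SNP against a whole *gene module* (a
co-expression cluster or a curated gene set) attacks both: per-gene signals
are aggregated, and the number of tests drops from tens of thousands of
genes to a few hundred modules.

The catch is that no single summary of a module is uniformly good. The
first principal component captures the dominant co-expression axis but is
blind to any signal orthogonal to it; a Bonferroni-corrected minimum over
per-gene tests (MinP) is strong only when one gene carries a large effect.
The omnibus approach implemented here evaluates six complementary
PC-combination statistics and corrects the best of them for selection.

## The test

For a module of $K$ genes with expression correlation matrix
$\Sigma_{K \times K}$, let $z$ be the vector of univariate association
Z scores of one SNP against the $K$ genes (under the null,
$z \sim N(0, \Sigma)$). With eigenpairs $(\lambda_k, \mu_k)$ of $\Sigma$,
the PC scores are

$$T_{PC_k} = \mu_k^\top z \sim N(0, \lambda_k),$$

independent across $k$ because eigenvectors are orthogonal. Only PCs with
$\lambda_k > 0.1$ are retained (default `lambda_min = 0.1`): near-degenerate
PCs carry essentially no signal but receive enormous weight in
variance-standardised statistics, destabilising the test. Retention can
never be empty since $\lambda_1 \ge 1$ for any correlation matrix.

Six statistics combine the $m$ retained scores ($p_k$ is the two-sided
p-value of $T_{PC_k}$):

* **PCMinP** $= \min_k p_k$, with exact null correction
  $1-(1-t)^m$ (the retained scores are independent);
* **PCFisher** $= -2\sum_k \log p_k \sim \chi^2_{2m}$;
* **Wald** $= \sum_k T_{PC_k}^2/\lambda_k \sim \chi^2_m$
  ($= z^\top\Sigma^{-1}z$ when all PCs are retained);
* **WI** $= \sum_k T_{PC_k}^2$ ($= z^\top z$ when all PCs are retained),
  a $\sum_k \lambda_k \chi^2_1$ mixture under the null;
* **VC** $= \sum_k \lambda_k T_{PC_k}^2$ ($= z^\top\Sigma z$), a
  $\sum_k \lambda_k^2 \chi^2_1$ mixture;
* **PCLC** $= \sum_k \lambda_k T_{PC_k}$, standardised by its null SD
  $\sqrt{\sum_k \lambda_k^3}$, two-sided normal.

These are the canonical Wald / unweighted / variance-component trio plus
the minimum, Fisher and linear combinations; they coincide when
$\Sigma = I$ and span sparse-strong through dense-weak signal
architectures. The omnibus statistic is $t = \min$ of the six p-values, and
the reported p-value corrects it for taking the best of six correlated
tests:

$$p = P\!\left(\min_j \Phi^{-1}(p_j) \le \Phi^{-1}(t_{obs})\right)
\quad \text{under the joint null.}$$

Because the linear combination (PCLC) changes sign with the eigenvectors,
a deterministic sign convention (largest-magnitude loading positive, ties
broken by lowest gene index) is applied; the quadratic statistics are
unaffected but reproducibility requires it.

### Numerical evaluation

The weighted chi-square tails of WI and VC are computed by Imhof's
inversion integral (adaptive quadrature, relative tolerance $10^{-6}$) with
a Lugannani–Rice saddlepoint taking over below $10^{-8}$, where the
oscillatory integral cannot resolve the mass but the saddlepoint keeps
relative accuracy. Batch evaluation interpolates a monotone spline of
$\log p$ against $\sqrt{x}$ through exact nodes (relative error
$\sim 10^{-4}$ or better, far below Monte-Carlo scales); duplicated
eigenvalues are collapsed into multiplicities before quadrature, which
makes block-structured matrices cheap.

The omnibus null is calibrated by Monte Carlo ([pco_calibrate()]): $B$
draws $z \sim N(0,\Sigma)$ (default $B = 10^5$) yield the exact joint null
sample of the six component p-values. Two artefacts of that sample are
used:

1. the empirical distribution of the null omnibus statistic, which
   evaluates $p$ in the bulk exactly in distribution (resolution $\sim 1/B$);
2. the $6\times 6$ correlation matrix of the $\Phi^{-1}$-transformed
   component p-values, which drives a multivariate-normal
   inclusion–exclusion series (deterministic bivariate/trivariate orthant
   terms) for the deep tail, ratio-matched to the empirical curve at the
   splice rank (the 100th smallest null statistic) so the two regimes agree.

Components whose transformed statistics correlate above 0.9999 in
calibration (e.g. Wald = WI = VC under an identity $\Sigma$, or everything
for $K = 1$) are merged so the correlation matrix stays non-singular.
Every reported p-value is clamped into the sandwich
$[t, \min(1, 6t)]$ — the omnibus correction can never beat the best
component, nor exceed its Bonferroni bound — and p-values are floored at
$10^{-300}$.

A purely multivariate-normal evaluation (a Gaussian copula on the six
components) was measured to be 5–10% off in the bulk of the distribution,
enough to fail uniformity tests at 20,000 draws; the hybrid above keeps
the bulk exact and uses the copula only where it is accurate enough
relative to everything else (the far tail).

```{r omnibus-example}
sigma <- make_block_sigma(c(2, 1), rho_within = 0.5)
model <- pco_model(sigma)
calib <- pco_calibrate(model, draws = 2e4, seed = 7)
pco_test(c(1.8, 1.2, -0.4), model, calib)
```

## The scanning pipelines

**Individual-level scan** ([genome_scan()]): univariate Z scores are the
Wald statistics of per-SNP-per-gene simple regressions, computed through
the correlation and the t-to-normal quantile bridge. For each SNP–module
pair, module genes on the SNP's chromosome are removed before testing so
cis effects cannot masquerade as trans; the PC model and its calibration
are re-derived on the surviving genes and cached per (module, surviving
set). Multiple testing uses a permutation null: genotype sample labels are
permuted (one shared permutation per pass, default 10 passes), the entire
scan re-run, and all p-values pooled. The empirical FDR is the pooled
plug-in estimate
$q(t) = \frac{\#\{p_{null} \le t\}/n_{perm}}{\max(1, \#\{p_{obs} \le t\})}$,
monotonised by a running minimum from the largest p downward. Significant
SNPs are grouped into LD-independent loci by greedy clumping (best-p lead
absorbs everything with $R^2 \ge 0.2$).

Permuting genotype labels (rather than expression) preserves the
expression correlation structure that the test conditions on; this
matches standard eQTL permutation practice.

One property of the pooled plug-in estimator deserves emphasis: with
$n_{perm}$ permutations the q-value at observed rank $r$ only takes values
in multiples of $1/(n_{perm}\, r)$, so whenever the smallest observed
p-value undercuts (nearly) the whole pool the estimate is 0 (or exactly
the level) regardless of how unremarkable that minimum is in absolute
terms. On a completely null scan of several hundred tests against a
10-permutation pool this produces at least one boundary call in roughly a
sixth of datasets — a resolution limit of the estimator itself, not a
miscalibration of the test (the underlying p-values are uniform). More
permutations sharpen it; the default of 10 trades that sharpness for scan
cost.

**Summary-statistics scan** ([sumstats_scan()]): when only SNP-by-gene Z
scores are available, $\Sigma$ is approximated by the correlation of Z
scores across *null SNPs* — SNPs with $|Z| < 1.96$ (per-gene two-sided
$p > 0.05$, configurable) on every module gene. The estimate is repaired
to positive definite (eigenvalue floor $10^{-6}$, rescaled to unit
diagonal). A module is only scanned when the ratio of null SNPs to module
size exceeds 50: below that the noisy estimate visibly inflates the test
statistics (the acceptance suite reproduces the inflation-versus-ratio
curve, with genomic inflation $\lambda_{GC}$ within $[0.9, 1.1]$ at ratios
$\ge 50$). Before each test, genes cross-mappable to any gene within
100 kb of the SNP (closed interval, gene-span overlap, 1-based inclusive
coordinates) are excluded along with same-chromosome genes — mis-assigned
reads from a cis gene to a homologous trans gene would otherwise fake a
trans signal. Significance uses Bonferroni correction across tests
performed, or the empirical FDR machinery when a null pool is supplied.

The module-level $\hat\Sigma$ is subset to the surviving genes per SNP
(not re-estimated), trading a small approximation for a large shared
cache.

## Preprocessing and modules

Counts are converted to TPM; expression is quantile normalised across
samples and then inverse-normal transformed per gene
($\Phi^{-1}((r-\tfrac12)/N)$, average ranks for ties); known covariates
(genotype PCs, expression PCs, cell-type proportions) are regressed out
with an implicit intercept before module detection and testing. Genes are
kept only if protein-coding or lincRNA with gene-level mappability 1.0 by
default — low-mappability genes attract multi-mapped reads and correlate
spuriously with their homologs. SNP QC drops variants at call rate
$\le 0.99$, MAF $\le 0.05$ or Hardy–Weinberg $p < 10^{-6}$ (exact test on
hard calls up to 1000 samples, chi-square beyond).

Note that with a finite gene panel, sample-wise quantile normalisation
leaves every matrix value on a shared grid, so gene columns contain ties
and the inverse-normal margins are exact only up to tie effects; with
transcriptome-scale gene counts these are negligible. Re-applying the
normalisation reproduces each gene's value grid exactly and its ranks
almost exactly (rank crossings between nearly-tied samples are possible),
so the pipeline is idempotent in practice but not bit-exactly.

Modules come either from average-linkage hierarchical clustering on
$1 - |\mathrm{cor}|$ with a 0.5 cut height and a minimum module size of 10
(a deliberately plain correlation clustering — module definitions are an
exchangeable input), or from GMT files of curated sets. Gene-level
mappability scores and cross-mappability pair tables are plain TSV inputs;
read-level filtering of alignments is out of scope for this package.

## The simulation framework

[simulate_null_z()] and [simulate_alt_z()] generate summary-statistic
panels directly: null rows $N(0, \Sigma)$; alternative rows
$N(\sqrt{n}\,\beta, \Sigma)$ with point-normal effects — a proportion
$\gamma$ of genes (uniformly placed per SNP, $\mathrm{round}(\gamma K)$,
at least one when $\gamma > 0$) receive $\beta_k \sim N(0, \sigma_b^2)$.
The $\sqrt{n}$ mean scaling is the score-statistic asymptotic for a
standardised per-allele effect: the variance a causal gene explains is
$\beta^2 \cdot 2f(1-f)$ for allele frequency $f$, and the corresponding Z
mean grows with the square root of the sample size. The default study
conditions are $n = 500$, $\gamma = 0.3$, $\sigma_b^2 = 0.001$ (a low,
realistic per-SNP trans heritability), 10,000 SNPs and 1,000 replicates;
the desk-scale preset used by the test-suite and the acceptance script is
2,000 SNPs with 40–100 replicates, which separates the methods by far more
than its Monte-Carlo error.

Power is the proportion of alternative SNPs called significant at 10%
empirical FDR, where the null distribution comes from 10 matched null
panels per replicate — the same machinery as the permutation FDR in the
scan. Comparators: **PC1** tests only $T_{PC_1} \sim N(0, \lambda_1)$;
**MinP** is the Bonferroni minimum over per-gene p-values,
$\min(1, K \min_k p_k)$.

```{r power-example, eval = FALSE}
sigma <- make_block_sigma(c(50, 51), rho_within = 0.7)
cfg <- simulation_config(n = 500, gamma = 0.3, sigma_b2 = 0.001,
                         n_snps = 2000, n_reps = 20, seed = 1)
run_power_study(sigma, cfg)
```

On the synthetic 101-gene module (two blocks, within-block correlation
0.7) the omnibus test dominates both comparators by a wide margin, PC1 is
nearly powerless (dense weak effects rarely align with the leading
eigenvector), and MinP only becomes competitive when a single gene carries
a large effect — exactly the architecture Bonferroni is built for.

## What the synthetic data does and does not emulate

The generator produces Hardy–Weinberg binomial dosages (optionally with
AR(1) latent correlation for LD-clumping tests), multivariate-normal
expression noise with block-equicorrelated module structure, and exactly
recorded planted effects, all bit-reproducible from a seed. It does not
emulate: realistic LD panels, count-level sequencing noise or library-size
effects, heavy-tailed expression, cell-type mixtures, or empirical
correlation spectra (real modules have smoothly decaying eigenvalues;
equicorrelated blocks have degenerate ones). Two consequences matter for
interpreting the tests. First, absolute power on a synthetic module is not
comparable to power on a real cohort's module — the correlation spectrum
drives it. Second, degenerate eigenvalue blocks make eigenvectors (and the
rotation-variant components PCMinP, PCFisher, PCLC) unidentifiable under
estimation noise, so individual-level and summary-statistics p-values for
the same SNP agree only approximately; agreement improves steadily with
the null-SNP ratio and is driven by the rotation-invariant quadratic
components. The test-suite checks convergence with ratio rather than a
fixed agreement rate.

## Numerical choices and degenerate inputs

* Calibration draws: default $10^5$ per model; genome scans default to
  $2\times10^4$ per (module, exclusion subset), sufficient because the
  per-subset null only needs the 6-component correlation and the bulk
  ECDF. The acceptance suite's oracle comparisons use $10^6$ to push the
  method's own Monte-Carlo error below the comparison's.
* All randomness flows through explicit integer seeds; child streams are
  derived by a deterministic string hash below $2^{31}$.
* Degenerate correlation estimates (rank-deficient, from few null SNPs or
  duplicated rows) are repaired by eigenvalue clipping and diagonal
  rescaling; a module whose genes are all excluded for a SNP produces a
  skipped record with a reason code, never an error mid-scan.
* p-value underflow clamps at $10^{-300}$ with a warning.
* Ties in ranks use average ranks; ties on p in LD clumping break by
  genomic order.

## Limitations

The omnibus test reports that a SNP perturbs a module, not which genes
drive the signal; per-gene follow-up on the univariate Z scores is the
intended exploratory route. Power depends on the module's correlation
spectrum, so absolute power numbers only transfer between datasets with
similar spectra. The summary-statistics mode inherits whatever read
mis-assignment is baked into the input Z scores; the cross-mappability
exclusion reduces but cannot eliminate it.
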