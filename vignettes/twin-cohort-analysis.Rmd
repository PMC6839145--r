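---
title: "Paired differential expression and methylation integration in discordant twin cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired differential expression and methylation integration in discordant twin cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Why a paired twin model

Monozygotic co-twins share genotype, age, sex and family environment. When
one twin is affected and the other is not, within-pair molecular differences
cannot be explained by genetic background, so a paired analysis of
discordant twins isolates non-shared environmental and stochastic signal.
`twindiff` implements the two analyses such a cohort supports: a
*discordant-group* analysis restricted to complete discordant pairs, and a
*case-control* analysis over all complete pairs (discordant, concordant-case
and control), where the case effect is identified by the within-discordant-
pair contrasts while the pair terms absorb all shared structure.

## The count model

For gene $g$ and sample $s$,

$$y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi_g), \qquad
\log \mu_{gs} = \alpha_{p(s)} + \beta_g\, x_s + \log(N_s f_s),$$

with $x_s$ the binary case status, $\alpha_{p(s)}$ a coefficient per twin
pair, $N_s$ the library size and $f_s$ its TMM normalisation factor. The
variance is $\mu + \phi\mu^2$. The reported log2 fold change is
$\beta_g/\ln 2$. The case effect is tested by a likelihood-ratio test of the
full against the case-dropped model, both fitted with the same per-gene
dispersion and offsets, against $\chi^2_1$. We use the plain LRT rather than
a quasi-likelihood F-test; at very small sample sizes this choice is known
to be slightly liberal in the extreme tail (see *Limitations*).

### Fitting

Each gene is fitted by Fisher-scoring IRLS with step halving on the
log-likelihood, converging when the log-likelihood changes by less than
$10^{-8}$ (at most 100 iterations). Non-convergence is flagged per gene,
never silently dropped. All-zero genes are handled exactly: the likelihood
tends to 0 as $\mu \to 0$, both nested fits agree, and the LRT p-value is 1.
The per-gene loops are compiled (RcppArmadillo), which keeps a full
2000-gene cohort analysis within a few seconds on one core.

### Dispersion estimation

Dispersions are estimated from the Cox–Reid adjusted profile likelihood
$\mathrm{APL}_g(\phi) = \ell(\hat\beta(\phi);\phi) -
\tfrac12 \log\det(X^\top W X)$ evaluated on a fixed log2-spaced grid,
$2^{-20} \dots 2^{5}$ in 41 points, with quadratic interpolation of the
maximiser on the log2 scale. Three estimators are derived: the *common*
maximiser of the summed APL; a *trend* from maximising the bin-averaged APL
in 20 equal-occupancy bins of average logCPM; and *tagwise* values
maximising $\mathrm{APL}_g + (d_0/d_\mathrm{res})\,\overline{\mathrm{APL}}_{\mathrm{bin}(g)}$,
where $d_0$ is `prior_df` (default 10) and $d_\mathrm{res}$ the residual
degrees of freedom, so the prior is expressed in genes-worth of information.
Tagwise values are constrained to lie between the per-gene maximiser and the
trend. `prior_df = 0` recovers the per-gene estimate and large `prior_df`
the trend. This is a deliberately specified simplification of the reference
empirical-Bayes machinery: acceptance is by parameter recovery (a constant
simulated $\phi = 0.2$ is recovered within $[0.15, 0.25]$), not numerical
identity with any package.

### Normalisation

TMM with the canonical trim fractions: 30% of each tail of the log-ratios
M, 5% of each tail of the average abundances A, precision weights from the
delta method, factors rescaled to geometric mean 1, reference sample chosen
as the one whose CPM upper quartile is closest to the mean upper quartile.
The implementation is validated both against a literal re-implementation of
the trimmed weighted mean (to $10^{-10}$) and against edgeR's
`calcNormFactors` (to $10^{-6}$) on random data.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_cpm`, `min_samples` | 1, 3 | CPM, samples | low-expression filter: keep genes at ≥ 1 CPM in ≥ 3 samples |
| logCPM prior count | 0.5 | counts | keeps zeros finite; `2*prior` added to the library size |
| `prior_df` | 10 | df | dispersion shrinkage weight |
| FDR threshold | 0.1 | — | discovery-oriented reporting level |
| SLK `dist` | 2000 | bp | spatial window for combining CpG evidence |
| ACF `bin_width` | 500 | bp | 4 distance bins to 2000 bp; bins with < 10 pairs borrow from the nearest populated bin |
| `top_k` | 20 | genes | size of the highlighted combined-evidence slice |
| `n_perm` (gene sets) | 10000 | draws | permutation floor $1/(n_{\mathrm{perm}}+1)$ |
| SVA `n_perm`, `alpha` | 100, 0.05 | — | Buja–Eyuboglu component selection |

## What the synthetic cohort emulates

`simulate_cohort()` generates the study conditions used throughout the test
suite: 16 complete MZ pairs (5 discordant, 4 concordant-case, 8 control;
singletons optional and excluded from paired analyses), 2000 genes with
baseline abundance uniform on 0–10 logCPM, NB dispersions from
Gamma(shape 2, rate 10) (mean 0.2, typical for blood RNA-seq), per-pair
per-gene shared effects of sd 0.5 log2 units — which reproduce the
qualitative twin signature that within-pair correlation exceeds
between-unrelated correlation — and 50 differentially expressed genes at
log2 fold change 2 in cases. The generative mean uses a natural-log link
with offset $\log(N_s/10^6)$, so baselines are interpretable as logCPM.
Library-size offsets are drawn from 1–2 million, a desk-scale stand-in for
deeply sequenced libraries that keeps the full suite fast.

The methylation layer emulates a sparse array: probes per gene are Poisson
(mean 3), spaced 500 bp apart, with AR(1) noise along the genome
($\rho = 0.6$, marginal sd 0.5 M-units) — the minimal spatial model that
makes the autocorrelation estimate of the SLK stage non-trivial — and a case
shift of 1.5 M-units for differentially methylated genes. Ten genes are
*linked* (effects in both assays); the differentially methylated set is the
linked genes plus an equal number of expression-null genes, so methylation
evidence alone does not imply differential expression.

What the generator does **not** emulate: cell-type composition shifts,
batch structure (unless planted explicitly in tests), GC/length biases,
alternative splicing, probe cross-hybridisation, or genuine biological
co-expression networks. Passing tests therefore demonstrate the pipeline's
statistical behaviour under its own model assumptions, not robustness to
every artefact of real data.

## The integrative analysis

Beta values are clamped to $[10^{-6}, 1-10^{-6}]$ on load (with a warning)
and transformed to M-values $\log_2(\beta/(1-\beta))$, which are better
behaved for linear modelling. Each probe is tested by ordinary least squares
on the same paired design as the expression model, with a two-sided t-test
on the case coefficient and no variance moderation. (The source workflow
nominally fitted these models inside a count framework; OLS on M-values is
what "a linear model" on array data describes, and is implemented here,
with this divergence documented.)

Spatial adjustment follows the Stouffer–Liptak–Kechris scheme: one-sided
z-scores $z = \Phi^{-1}(1-p)$, a distance-binned autocorrelation estimated
from all same-chromosome probe pairs within 2000 bp (negative estimates
floored at 0), and for each probe the combined
$z = \sum_j z_j / \sqrt{\sum_{jk}\sigma_{jk}}$ over its ±2000 bp
neighbourhood. An isolated probe keeps its raw p-value exactly. Gene-level
methylation evidence is the minimum adjusted p over the gene's probes —
a ranking statistic, deliberately not multiplicity-adjusted. Region calling
(the seeding/merging step some spatial-correction tools add) is not on the
main path because the gene summary uses per-CpG adjusted p-values.

Expression and methylation p-values are combined by the empirical Brown
method: evidence scores $w(s) = -2\ln(\mathrm{rank}(v_s)/n)$ (maximum-rank
ties, so the largest observation maps to 0 — an off-by-one in the ECDF
convention changes the covariance, hence it is pinned down here), covariance
$c = \mathrm{cov}(w_x, w_y)$ over shared samples, Brown moments $E = 4$,
$\mathrm{Var} = 8 + 2c$, and a scaled-$\chi^2$ reference for Fisher's
statistic. With $c = 0$ this is exactly Fisher's method. The per-gene data
vectors are the gene's normalised CPM and its median Beta across probes —
the same operands as the reported Spearman correlation. Using one global
assay-wide covariance instead of per-gene vectors was considered and left as
a non-default option: per-gene vectors follow the "uses the assay data"
reading and adapt to gene-specific dependence.

## Surrogate variables

The estimator residualises logCPM against the design, takes the SVD of the
residuals, and keeps the leading right singular vectors whose variance
fractions exceed the $1-\alpha$ quantile of the same fraction under
row-wise permutations (re-residualised, so permuted and observed spectra are
comparable). This two-step variant replaces the iterative reweighting of the
full SVA because the package uses surrogate variables only for sensitivity
reruns, and the simplified estimator is fully specifiable and testable: a
planted design-orthogonal batch is recovered with $|r| > 0.8$ and pure noise
yields zero components in ≥ 90% of runs.

## Numerical choices and degenerate inputs

* Ties in DE tables are broken by gene id for deterministic output; the
  rank-based set test uses average ranks.
* The mean-rank set test is one-sided towards significance (low mean rank),
  with permutation subsets drawn from the post-filter analysis universe,
  not the genome; `p = (1 + \#\{T^* \le T\})/(n_{\mathrm{perm}}+1)`.
  A rotation-based pathway test is intentionally not implemented; pathway
  collections reuse the same permutation machinery and results carry a
  method tag so they cannot be misread.
* Outlier flagging is advisory (median correlation below median − 3 MAD);
  sample removal requires an explicit option and always removes whole
  pairs. The underlying study removed outliers by visual inspection, which
  a pipeline cannot reproduce; the MAD rule is this package's own.
* Probes constant across samples get effect 0, p = 1 and a `degenerate`
  flag; constant vectors in the Brown combination fall back to
  independence with a warning.
* In the case-control design, concordant pairs make `case` constant within
  their block; the design remains full rank while at least one discordant
  pair is present. Aliased columns are pivoted out with a warning; an
  aliased `case` is an error.
* Per-pair fold changes use a 0.5-count, 1-read shrinkage:
  $\log_2\frac{y_1+0.5}{N_1 f_1+1} - \log_2\frac{y_2+0.5}{N_2 f_2+1}$;
  control and concordant pairs are contrasted in sample-sheet order.

## Problem sizes

The test suite and the acceptance script run entirely on simulated cohorts
of 2000 genes and 16 pairs (about 6000 CpG probes): large enough for stable
calibration estimates at desk scale, small enough that the whole suite runs
in a few minutes on one core. Replicated checks use 10–20 seeded
replicates.

## Limitations

* With 5 discordant pairs (10 samples) and heterogeneous true dispersions,
  shrunken-dispersion LRT p-values are slightly conservative in the bulk
  and slightly liberal in the extreme tail; the realised false discovery
  proportion at BH 10% runs above nominal (around 0.2 in simulation). This
  matches the behaviour of the reference count-model implementation on the
  same data and is a property of the design size, not of the
  implementation.
* Pooled within-pair |logFC| values are dependent across genes; the Welch
  and KS p-values comparing study groups are descriptive, and the result
  object carries that caveat explicitly.
* Methylation and expression are combined in *cis* at the gene level only;
  no causal direction between methylation, expression and trait is
  inferred.
* The KS p-value is asymptotic (appropriate for the tens of thousands of
  pooled values it is applied to); exact small-sample KS p-values are not
  implemented.
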