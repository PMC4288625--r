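---
title: "Building blood-based diagnostic gene signatures with Bayesian probit regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building blood-based diagnostic gene signatures with Bayesian probit regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bprsig)
```

## The problem

Idiopathic pulmonary fibrosis (IPF) is hard to diagnose: the standard route
combines clinical, radiological and pathological evidence, and a meaningful
fraction of interstitial lung disease remains unclassified. A peripheral-blood
transcriptomic classifier offers a less invasive alternative, both for
suspected sporadic IPF and for screening at-risk relatives in familial
interstitial pneumonia kindreds.

`bprsig` implements a complete pipeline for building such a *functional gene
signature* — not a mere list of differential genes, but a portable predictive
object: a feature list, the training-set factorization that summarizes those
features, a fitted regression with uncertainty, and a decision threshold.

## The model

Let $X$ be a normalized log2 expression matrix (features $\times$ samples)
and $y_i \in \{0, 1\}$ indicate disease. The pipeline is:

1. **Feature ranking.** Each gene is scored by the pooled-variance two-sample
   $t$ statistic (disease minus control); the top $k$ genes by $|t|$ form the
   candidate signature. The pooled standard deviation is floored at $10^{-8}$
   so constant genes rank deterministically at $t = 0$.

2. **Metagene summarization.** The selected $k \times n$ submatrix is centered
   per gene and decomposed as $X_c = U D V^\top$. The first two left singular
   vectors $U_2$ define two *metagenes*; any sample $x$ (training or new) is
   summarized by the factor scores $f = U_2^\top (x - \mu)$, where $\mu$ holds
   the training gene means. Training scores equal rows of $V D$ restricted to
   the first two components — the $D$-scaled convention, pinned down by the
   requirement that projecting a training column reproduces its stored score.

3. **Bayesian probit regression.** $P(y = 1 \mid f) =
   \Phi(\beta_0 + \beta_1 f_1 + \beta_2 f_2)$ with a diffuse
   $N(0,\, 10^6 I)$ prior on $\beta$ and the probit latent variance fixed
   at 1. The posterior is sampled by the Albert–Chib data-augmentation Gibbs
   sampler: truncated-normal latent draws given $\beta$, then a conjugate
   multivariate-normal draw of $\beta$ given the latents. A prediction is the
   posterior mean of $\Phi(\beta_0 + \beta^\top f)$ across retained draws,
   with a central 95% credible interval.

4. **Signature-size selection.** Sizes $k$ are swept over a contiguous range
   (classically 50–250). Each size is scored by fully nested leave-one-out
   cross-validation — feature ranking, factorization and regression are all
   redone on every fold's $n-1$ samples, so the held-out label never touches
   selection. Sizes are compared by LOOCV ROC AUC, ties broken by the sum of
   deviance, remaining ties by the smallest size.

5. **Thresholding and validation.** The final model predicts a held-out
   validation cohort; the decision threshold maximizes the Youden index
   $J = \text{sensitivity} + \text{specificity} - 1$ (ties resolved toward
   the larger, specificity-favoring threshold), and the report carries the
   confusion matrix, derived rates, and a two-sided Wilcoxon rank-sum test
   of the probability–phenotype association.

## Design choices in detail

**Severity and the cohort split.** Disease severity is MILD when FVC ≥ 75%
and DLCO ≥ 65% of predicted, SEVERE when FVC ≤ 50% and DLCO ≤ 35% (boundaries
inclusive), MODERATE otherwise; a single available measure decides alone, and
severity is UNKNOWN only when both are missing. The training/validation split
is stratified (controls, plus cases by severity) and systematic: within each
stratum, samples are sorted by id and every third one goes to validation. The
source study did not state its enumeration order or starting offset, and its
printed per-stratum validation counts cannot all be reproduced by any single
fixed-offset rule, so the offset is exposed as a parameter (default: positions
3, 6, 9, …) and the convention is documented rather than guessed at.

**Sum of deviance.** The tie-breaker is defined here as
$\mathrm{SOD} = \sum_i |y_i - p_i|$ — the aggregate distance between each
predicted probability and the ideal probability (1) of the true phenotype.
An absolute form is bounded, so a single confidently wrong LOOCV fold cannot
dominate the criterion the way it does under the binomial deviance
$-2\sum[y \log p + (1-y)\log(1-p)]$; the binomial form remains available via
`sum_of_deviance(..., method = "binomial")`.

**CoV filtering.** The coefficient-of-variation filter (keep the top decile
by $\mathrm{sd}/|\mathrm{mean}|$, computed on the supplied log2 scale) is used
for the unsupervised stage only; supervised feature selection draws from the
full feature set. Log-scale intensities on this platform are positive, which
is what makes the CoV well defined; a zero-mean feature with nonzero spread
is a hard error rather than a silent infinity.

**Priors and the latent variance.** "Non-informative" is implemented as a
proper but very diffuse normal prior, which keeps the Gibbs updates conjugate.
The probit latent variance is fixed at 1: a free latent scale is not
identifiable in a binary probit (only $\beta/\sigma$ is), so a scaled-probit
variant would add a random-walk dimension without changing predictions.

**MCMC settings.** Defaults are 6,000 iterations with 1,000 burn-in for final
models, 2,000/500 inside LOOCV sweeps (a 3-parameter conjugate sampler mixes
quickly, and a sweep can involve thousands of short chains). Chains are
seeded deterministically — fold $f$ uses `seed + f` — so every result in the
package is bit-reproducible. One caveat observed in testing: under complete
separation of the classes in factor space, the diffuse prior lets $\beta$
drift to large magnitudes through a slow random walk, so probabilities
saturate toward 0/1 only as chains lengthen. Rank-based quantities (AUC) are
insensitive to this; calibrated probabilities near the extremes require
longer chains. A Geweke-style drift check (batch-means z on $\beta_1$, warn
at $|z| > 4$) flags such chains.

## What the synthetic generator does and does not emulate

`generate_cohort()` draws per-gene baseline means uniformly on (6, 14) log2
units and per-gene standard deviations on (0.2, 1.5) — heteroscedastic,
microarray-like intensities. A configurable fraction of genes (default 2%)
receives a class shift of `effect_size_sd` gene-sds with random sign.
Clinical annotations mirror the emulated study's composition: 89 cases vs 26
controls, case severities mixed 23:44:14:8 (mild:moderate:severe:unknown),
sporadic:familial history 48:41, six processing batches. Pulmonary-function
values are drawn from boxes chosen so that `classify_severity()` reproduces
the sampled stratum exactly: mild from (76–115) × (66–105), moderate from
(55–74) × (40–64), severe from (25–49) × (15–34), healthy controls from
(85–120) × (75–110) — clinically plausible ranges where the emulated study
prints none. Batch offsets default to zero, matching that study's finding
that batches were indistinguishable in PCA.

The generator is Gaussian on the log2 scale: no heavy-tailed intensities, no
probe-level artifacts, no missing values, no gene–gene correlation beyond
what the class shifts induce. Tests passing on this substrate therefore
validate the *pipeline logic* — nesting, determinism, selection rules,
calibration of the sampler — not robustness to real microarray pathology.

## Numerical conventions

- CoV ties in filtering, and $|t|$ ties in selection, break by feature id;
  the split sorts ids within strata — all orderings are deterministic.
- `cov_filter` retains exactly `ceiling(top_fraction * n_features)` features.
- PCA centers features, never scales; variance fractions come from singular
  values of the centered matrix.
- Correlation distance for clustering is $1 - r$ with the sample ($n-1$)
  variance convention; UPGMA merges follow `stats::hclust(method = "average")`.
- A factorization requires numerical rank ≥ 2 after centering (second
  singular value above $10^{-12}$ of the first).
- Youden threshold candidates are the observed probabilities; calls use
  $p \ge t$, so a printed threshold is an attainable, inclusive cutoff.
- Credible intervals for predictions are central 95% quantiles, widened if
  necessary to contain the posterior-mean probability (under extreme skew a
  mean can otherwise sit just outside the quantile pair).

## Honesty of the nested cross-validation

The package deliberately exposes a *leaky* diagnostic mode
(`loocv_sweep(..., fixed_features = )`) in which the feature ranking is
computed once on all samples. On null cohorts (no differential genes,
n = 40, 2,000 features, sizes 50–80) the leaky mode reports mean LOOCV AUC
near 1 — the selection-bias artifact this design guards against — while the
nested mode stays near chance. Two properties of the honest estimator are
worth knowing:

- *Pessimistic drift.* On null data, nested LOOCV with within-fold selection
  is not centered exactly at AUC 0.5 but somewhat below it: leaving a sample
  out pulls the selected features' class means away from it, so null
  predictions anti-correlate with the truth. This is a known property of the
  estimator, not a defect of the implementation (the fixed-feature control
  above sits at 0.5).
- *High per-seed variance.* With n = 40 the pooled LOOCV probabilities are
  strongly coupled across folds, so single-cohort null AUCs range roughly
  0.15–0.8; only averages over many cohorts are stable.

## Problem sizes used in the shipped analyses

The `analysis/` scripts and the acceptance script run the full 22,078 ×
115 cohort but sweep signature sizes 50–120 with 2,000-iteration tuning
chains — a desk-scale choice that finishes in minutes while exercising every
stage at full feature dimension. The classical 50–250 sweep with longer
chains is one argument away (`k_max`, `iterations`).

## Known limitations

- Exactly two metagenes, as in the method this package operationalizes; no
  multi-factor or tree-structured extensions.
- The Gibbs sampler is single-chain; convergence monitoring is the Geweke
  drift heuristic, not multi-chain $\hat R$.
- No batch correction: the pipeline assumes (and the exploratory stage
  checks) that batches are unstructured.
- Validation here is *internal* to a cohort (held-out but same population);
  nothing in the package addresses transfer to external populations or
  platforms.
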